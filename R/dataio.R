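# Packaged study data and file I/O.

#' Load the packaged compound table
#'
#' The 17 PRMT1-inhibitor compounds of the study set: identifier, SMILES,
#' experimental IC50 in M/1e5 units (right-censored entries such as
#' `">20"` flagged), the experimental pIC50 column as published (kept
#' verbatim, including one entry inconsistent with its own IC50), a pIC50
#' recomputed from the IC50 for comparison, and the experimental activity
#' class (`A`: IC50 <= 1 and not censored, `I` otherwise).
#'
#' @return A tibble with 17 rows and columns `id`, `smiles`, `ic50`,
#'   `ic50_censored`, `pic50_exp`, `pic50_from_ic50`, `pic50_censored`,
#'   `class_exp`, with attribute `provenance = "table1"`.
#' @export
#' @examples
#' load_table1()
load_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "topoqsar",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, colClasses = "character")
  ic <- parse_ic50(raw$ic50)
  out <- tibble::tibble(
    id = raw$id,
    smiles = raw$smiles,
    ic50 = ic$ic50,
    ic50_censored = ic$ic50_censored,
    pic50_exp = as.numeric(raw$pic50_exp),
    pic50_from_ic50 = pic50_from_ic50(ic$ic50),
    pic50_censored = ic$ic50_censored,
    class_exp = raw$class_exp
  )
  attr(out, "provenance") <- "table1"
  out
}

#' Read a .smi file
#'
#' One record per line: a SMILES string, whitespace, an identifier. Lines
#' that are empty or start with `#` are skipped.
#'
#' @param path Path to the file.
#' @return A tibble with columns `id` and `smiles`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(lengths(parts) < 1)
  smiles <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else as.character(i)
  }, character(1))
  tibble::tibble(id = ids, smiles = smiles)
}

#' Read a compound CSV
#'
#' A CSV with at least `id` and `smiles` columns; `ic50` (possibly
#' censored, e.g. `">20"`) and `class_exp` are carried through and parsed
#' when present.
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_compounds <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(c("id", "smiles"), names(raw))
  if (length(missing)) {
    stop("compound CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  if ("ic50" %in% names(out)) {
    ic <- parse_ic50(out$ic50)
    out$ic50 <- ic$ic50
    out$ic50_censored <- ic$ic50_censored
  }
  out
}

#' Write / read a descriptor table
#'
#' Plain CSV interchange for descriptor tables: compound rows, descriptor
#' columns, stable column order, `.` decimal separator, header row. The
#' reader restores full double precision written by the writer.
#'
#' @param table A data frame as returned by [compute_descriptors()].
#' @param path Destination path.
#' @return `write_descriptors()` returns `path` invisibly;
#'   `read_descriptors()` returns a tibble.
#' @export
write_descriptors <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8",
                                    check.names = FALSE))
}

#' Read or write a linear model as JSON
#'
#' Models are interchanged as JSON objects with fields `kind`, `intercept`
#' and `coefficients` (a name-to-value map). The package ships the two
#' published equations as `eq1.json` (discriminant) and `eq2.json`
#' (regression); see [eq1_model()] and [eq2_model()].
#'
#' @param path Path to a JSON file.
#' @return A [linear_model].
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  missing <- setdiff(c("kind", "intercept", "coefficients"), names(obj))
  if (length(missing)) {
    stop("model file lacks field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  linear_model(obj$kind, obj$intercept, unlist(obj$coefficients))
}

#' @rdname read_model
#' @param model A [linear_model] to serialize.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "linear_model"))
  jsonlite::write_json(
    list(kind = model$kind, intercept = model$intercept,
         coefficients = as.list(model$coefficients)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' The shipped discriminant and regression equations
#'
#' `eq1_model()` is the published linear discriminant function on `nDB`,
#' `nN`, `GGI9` and `JGI4`; `eq2_model()` is the published multilinear
#' regression of pIC50 on `JGI4`, `GGI7`, `Mv` and `X0v`.
#'
#' @return A [linear_model].
#' @export
eq1_model <- function() {
  read_model(system.file("extdata", "eq1.json", package = "topoqsar",
                         mustWork = TRUE))
}

#' @rdname eq1_model
#' @export
eq2_model <- function() {
  read_model(system.file("extdata", "eq2.json", package = "topoqsar",
                         mustWork = TRUE))
}
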