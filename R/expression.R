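#' Create an expression profile
#'
#' An expression profile is a two-column tibble (`gene`, `rpkm`) tagged
#' with a label and a group (`"cancer"`, `"healthy"` or `"unlabeled"`).
#' RPKM values drive the flux bound rule and must be non-negative.
#'
#' @param values Named numeric vector of RPKM values, or a data frame
#'   with columns `gene` and `rpkm`.
#' @param label Profile label (e.g. a cell line or tissue name).
#' @param group One of `"cancer"`, `"healthy"`, `"unlabeled"`.
#' @return A tibble of class `expression_profile` with attributes
#'   `label` and `group`.
#' @export
expression_profile <- function(values, label = "profile",
                               group = c("unlabeled", "cancer", "healthy")) {
  group <- match.arg(group)
  if (is.data.frame(values)) {
    stopifnot(all(c("gene", "rpkm") %in% names(values)))
    tbl <- as_tibble(values[, c("gene", "rpkm")])
  } else {
    if (is.null(names(values))) abort("`values` must be named by gene")
    tbl <- tibble(gene = names(values), rpkm = as.numeric(values))
  }
  if (any(is.na(tbl$rpkm))) abort("non-numeric or missing RPKM value")
  if (any(tbl$rpkm < 0)) {
    abort(paste0("negative RPKM for gene: ",
                 paste(tbl$gene[tbl$rpkm < 0], collapse = ", ")))
  }
  if (anyDuplicated(tbl$gene)) {
    warn("duplicate gene rows; keeping the maximum RPKM per gene")
    tbl <- tbl |>
      group_by(.data$gene) |>
      summarise(rpkm = max(.data$rpkm), .groups = "drop")
  }
  structure(tbl, class = c("expression_profile", class(tbl)),
            label = label, group = group)
}

#' Read an expression profile from a delimited file
#'
#' Expects a header-bearing two-column table `gene<TAB>rpkm` (or comma
#' separated; the delimiter is auto-detected from the header line).
#' Duplicate genes keep their maximum value with a warning; negative or
#' non-numeric values are errors.
#'
#' @param path Path to a TSV/CSV file.
#' @inheritParams expression_profile
#' @return An [expression_profile()].
#' @export
read_expression_profile <- function(path, label = NULL,
                                    group = "unlabeled") {
  if (!file.exists(path)) abort(paste0("cannot read profile: ", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort("empty expression file")
  delim <- if (grepl("\t", first)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, col_types = "cc",
                           col_names = TRUE, trim_ws = TRUE)
  if (ncol(tbl) < 2L || nrow(tbl) == 0L) {
    abort("expression file needs a header and two columns: gene, rpkm")
  }
  rpkm <- suppressWarnings(as.numeric(tbl[[2]]))
  if (any(is.na(rpkm))) {
    abort(paste0("non-numeric RPKM value in row(s): ",
                 paste(which(is.na(rpkm)), collapse = ", ")))
  }
  expression_profile(setNames(rpkm, tbl[[1]]),
                     label = label %||% basename(path), group = group)
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile> ", attr(x, "label"), " (",
      attr(x, "group"), "), ", nrow(x), " genes\n", sep = "")
  NextMethod()
}
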