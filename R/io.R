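# Delimited-text effect-size tables. Header:
#   study_id,smd,se[,n_students,n_clusters_t,n_clusters_c,cluster_size]
# `se` may be replaced by `variance` or `weight`; exactly one of the three
# is required and the others are derived.

effect_optional_cols <- c("n_students", "n_clusters_t", "n_clusters_c",
                          "cluster_size")

#' Read an effect-size table
#'
#' Reads a delimited (comma-separated, UTF-8, decimal-point) effect-size
#' table into a meta-analytic tibble. The uncertainty column may be given
#' as `se`, `variance` (se is its square root), or `weight` (se is
#' `1/sqrt(weight)`); exactly one must be present. Optional sample-size
#' columns are kept.
#'
#' @param path Path to the file.
#' @return A validated meta-analytic tibble (see [validate_meta()]).
#' @export
read_effect_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"study_id" %in% names(raw) || !"smd" %in% names(raw)) {
    abort("effect table must have `study_id` and `smd` columns.")
  }
  unc <- intersect(c("se", "variance", "weight"), names(raw))
  if (length(unc) != 1) {
    abort(paste0("exactly one of `se`, `variance`, `weight` is required; found ",
                 if (length(unc) == 0) "none" else paste(unc, collapse = ", "),
                 "."))
  }
  for (col in c("smd", unc)) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      bad_rows <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      abort(paste0("non-numeric `", col, "` at row(s): ",
                   paste(bad_rows, collapse = ", "), "."))
    }
    if (anyNA(v)) {
      abort(paste0("missing `", col, "` at row(s): ",
                   paste(which(is.na(v)), collapse = ", "), "."))
    }
  }
  se <- switch(unc,
               se = raw$se,
               variance = sqrt(raw$variance),
               weight = 1 / sqrt(raw$weight))
  out <- tibble::tibble(study_id = as.character(raw$study_id),
                        smd = raw$smd, se = se)
  for (col in intersect(effect_optional_cols, names(raw))) {
    out[[col]] <- raw[[col]]
  }
  validate_meta(out)
}

#' Write an effect-size table
#'
#' Writes a meta-analytic tibble to the delimited-text effect-size format
#' (header always emitted; full numeric precision, so
#' `read_effect_table(write_effect_table(d, f))` round-trips exactly).
#'
#' @inheritParams validate_meta
#' @param path Output path; the directory must be writable.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(data, path) {
  data <- validate_meta(data)
  cols <- c("study_id", "smd", "se",
            intersect(effect_optional_cols, names(data)))
  readr::write_csv(data[, cols], path, progress = FALSE)
  invisible(path)
}
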