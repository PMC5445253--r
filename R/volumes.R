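#' Construct a regional volume table
#'
#' A volume table holds one row per subject: a `subject_id`, one raw
#' volume column (mm^3) per measure of a parcellation scheme, and the
#' subject's total intracranial volume `tiv` (mm^3).  A `whole_brain`
#' column is accepted and carried along but never used by the pipeline.
#'
#' @param df Data frame with `subject_id`, `tiv` and one column per
#'   measure in `scheme`.
#' @param scheme A `parcellation_scheme`; defaults to
#'   [default_parcellation()].
#' @return The data frame, validated and classed `volume_table`, with
#'   the scheme attached as attribute `"scheme"`.
#' @export
volume_table <- function(df, scheme = default_parcellation()) {
  scheme <- validate_parcellation(scheme)
  stopifnot(is.data.frame(df))
  need <- c("subject_id", scheme$measure, "tiv")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("volume table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(df), c(need, "whole_brain"))
  if (length(unknown))
    stop("volume table has unknown column(s): ",
         paste(unknown, collapse = ", "))
  df <- df[, intersect(c(need, "whole_brain"), names(df))]
  vols <- as.matrix(df[, scheme$measure, drop = FALSE])
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("all regional volumes must be positive and finite")
  if (any(vols > df$tiv))
    stop("no regional volume can exceed the subject's tiv")
  attr(df, "scheme") <- scheme
  class(df) <- c("volume_table", "data.frame")
  df
}

#' Normalise regional volumes to percent of total intracranial volume
#'
#' Expresses every regional measure as `100 * volume / tiv`, removing
#' head-size differences between subjects.  Subjects whose `tiv` is
#' missing or non-positive are dropped with a message.
#'
#' @param raw A `volume_table`.
#' @return A `normalized_volume_table`: `subject_id` plus one
#'   percent-of-TIV column per measure; row order preserved.
#' @examples
#' sch <- validate_parcellation(
#'   data.frame(measure = c("x_l", "x_r"),
#'              hemisphere = c("left", "right"),
#'              class = "cortical", structure = "x"))
#' vt <- volume_table(
#'   data.frame(subject_id = "s1", x_l = 70000, x_r = 71000,
#'              tiv = 1400000), sch)
#' normalize_to_tiv(vt)  # x_l = 5.0 percent
#' @export
normalize_to_tiv <- function(raw) {
  stopifnot(inherits(raw, "volume_table"))
  scheme <- attr(raw, "scheme")
  bad <- !is.finite(raw$tiv) | raw$tiv <= 0
  if (any(bad)) {
    message(sum(bad), " subject(s) dropped: tiv missing or non-positive (",
            paste(utils::head(raw$subject_id[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "", ")")
    raw <- raw[!bad, , drop = FALSE]
  }
  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  for (m in scheme$measure) out[[m]] <- 100 * raw[[m]] / raw$tiv
  attr(out, "scheme") <- scheme
  class(out) <- c("normalized_volume_table", "data.frame")
  out
}

#' Read / write volume tables
#'
#' Volume tables are exchanged as comma-separated UTF-8 text with a
#' header row; missing values are empty fields.  Column order in the
#' file is free; the table is returned in scheme order.
#'
#' @param path File path.
#' @param scheme A `parcellation_scheme`.
#' @return `read_volume_table` returns a `volume_table`.
#' @export
read_volume_table <- function(path, scheme = default_parcellation()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  volume_table(df, scheme)
}

#' @rdname read_volume_table
#' @param x A `volume_table` (or normalised table) to write.
#' @export
write_volume_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}
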