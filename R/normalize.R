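# Control-based normalisation of probe intensities to log2 ratios.
# Two modes: a scalar linear fit against the per-probe control median
# (conumee-style), and a tangent projection onto the span of the control
# profiles (conumee2-style).

check_intensity <- function(m, what) {
  if (!is.matrix(m)) stop_fmt("%s must be a probes x samples matrix", what)
  if (any(m < 0)) stop_fmt("%s contains negative intensities", what)
  m
}

#' Linear-reference log2 ratios
#'
#' For each query sample, a single scale factor `a` is fitted by least squares
#' of the query intensities on the per-probe control median `r`
#' (`a = sum(q * r) / sum(r^2)`), and the per-probe log2 ratio
#' `log2(q / (a * r))` is returned. A global scaling of the query is therefore
#' absorbed by the fit. Probes whose control median is zero are dropped and
#' counted in a message.
#'
#' @param query Probes x samples matrix of non-negative combined
#'   (methylated + unmethylated) intensities.
#' @param controls Probes x samples matrix of control intensities, same probe
#'   order as `query`.
#' @return Probes x samples matrix of log2 ratios with attribute
#'   `normalization = "linear"`. Row names follow `query`.
#' @export
linear_reference_log2 <- function(query, controls) {
  query <- check_intensity(query, "query")
  controls <- check_intensity(controls, "controls")
  if (nrow(query) != nrow(controls)) stop_fmt("query/control probe sets differ")
  r <- if (ncol(controls) == 1L) controls[, 1] else row_medians(controls)
  keep <- r > 0
  if (!any(keep)) stop_fmt("all control medians are zero")
  if (any(!keep)) {
    message(sprintf("dropping %d probe(s) with zero control median", sum(!keep)))
  }
  q <- query[keep, , drop = FALSE]
  r <- r[keep]
  a <- as.numeric(crossprod(r, q)) / sum(r^2)
  if (any(a <= 0)) stop_fmt("non-positive fitted scale; check query intensities")
  fitted <- outer(r, a)
  eps <- 1e-6 * stats::median(fitted)
  out <- log2(pmax(q, eps) / pmax(fitted, eps))
  dimnames(out) <- list(rownames(query)[keep], colnames(query))
  attr(out, "normalization") <- "linear"
  out
}

#' Tangent-normalised log2 ratios
#'
#' For each query sample, its intensity vector is projected (ordinary least
#' squares) onto the linear span of the control intensity vectors; the log2
#' ratio of query over fitted is returned. The fit is floored at a small
#' positive epsilon before the ratio so the output is finite.
#'
#' @inheritParams linear_reference_log2
#' @param eps_frac Floor for the fitted values, as a fraction of the median
#'   positive fitted value (default `1e-6`).
#' @return Probes x samples log2-ratio matrix with attribute
#'   `normalization = "tangent"`.
#' @export
tangent_log2 <- function(query, controls, eps_frac = 1e-6) {
  query <- check_intensity(query, "query")
  controls <- check_intensity(controls, "controls")
  if (nrow(query) != nrow(controls)) stop_fmt("query/control probe sets differ")
  if (ncol(controls) >= nrow(controls)) {
    stop_fmt("tangent normalisation needs fewer controls than probes")
  }
  dec <- qr(controls)
  if (dec$rank < ncol(controls)) {
    warn_fmt(
      "controls are rank deficient (rank %d of %d); projecting onto the span",
      dec$rank, ncol(controls)
    )
  }
  out <- matrix(NA_real_, nrow(query), ncol(query), dimnames = dimnames(query))
  for (s in seq_len(ncol(query))) {
    fitted <- qr.fitted(dec, query[, s])
    floor_at <- eps_frac * stats::median(fitted[fitted > 0])
    fitted <- pmax(fitted, floor_at)
    out[, s] <- log2(pmax(query[, s], floor_at) / fitted)
  }
  attr(out, "normalization") <- "tangent"
  out
}

#' Read a probe-level intensity or log2-ratio matrix TSV
#'
#' First column is `probe_id`; the remaining columns are samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with probe IDs as row names.
#' @export
read_probe_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "probe_id") stop_fmt("first column must be probe_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  storage.mode(m) <- "double"
  m
}
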