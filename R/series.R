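# The observation container handed to the HMM: per-segment step lengths,
# turning angles and aligned covariates.

#' Build a step/angle observation series
#'
#' One row per step (n - 1 rows for a segment of n fixes). The first angle
#' of a segment and angles adjacent to zero-length steps are missing (`NA`)
#' and contribute nothing to the likelihood. Covariate columns (e.g.
#' collar temperature) ride along and drive the transition matrix when the
#' model declares them.
#'
#' @param segment_id segment identifier per step (steps of one segment must
#'   be contiguous and in time order).
#' @param step_m step lengths, m per fix interval (>= 0).
#' @param angle_rad turning angles in (-pi, pi], `NA` where undefined.
#' @param covariates optional data.frame of per-step covariate columns.
#' @return data.frame of class `step_series`; attribute `p0` holds the
#'   fraction of exactly-zero steps.
#' @export
step_series <- function(segment_id, step_m, angle_rad = NULL,
                        covariates = NULL) {
  n <- length(step_m)
  if (is.null(angle_rad)) angle_rad <- rep(NA_real_, n)
  stopifnot(length(segment_id) == n, length(angle_rad) == n)
  if (any(step_m < 0, na.rm = TRUE)) stop("steps must be non-negative")
  bad <- !is.na(angle_rad) & (angle_rad <= -pi | angle_rad > pi)
  if (any(bad)) stop("angles must lie in (-pi, pi] or be NA")
  df <- data.frame(segment_id = segment_id, step_m = step_m,
                   angle_rad = angle_rad)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    df <- cbind(df, covariates)
  }
  attr(df, "p0") <- if (n) mean(step_m < 1e-6, na.rm = TRUE) else NA_real_
  class(df) <- c("step_series", "data.frame")
  df
}

as_step_series <- function(df) {
  cov_cols <- setdiff(names(df), c("segment_id", "step_m", "angle_rad", "idx"))
  step_series(df$segment_id, df$step_m, df$angle_rad,
              if (length(cov_cols)) df[cov_cols] else NULL)
}

# matrices handed to the C++ kernels
series_matrices <- function(data, covariates = character(0)) {
  if (!all(covariates %in% names(data)))
    stop("series lacks declared covariate column(s): ",
         paste(setdiff(covariates, names(data)), collapse = ", "))
  seg <- as.integer(factor(data$segment_id, levels = unique(data$segment_id)))
  covar <- if (length(covariates))
    as.matrix(data[covariates]) else matrix(0, nrow(data), 0)
  if (length(covariates) && any(!is.finite(covar)))
    stop("covariate columns must be finite (impute or drop missing values first)")
  list(step = as.numeric(data$step_m), angle = as.numeric(data$angle_rad),
       seg = seg, covar = covar)
}

#' Write a step/angle series to CSV
#'
#' Columns: segment_id, idx, step_m, angle_rad plus covariates; missing
#' angles are written as empty cells.
#' @param data a `step_series`.
#' @param path output path.
#' @param provenance optional comment line written before the header.
#' @export
write_series_csv <- function(data, path, provenance = NULL) {
  idx <- stats::ave(seq_len(nrow(data)), data$segment_id,
                    FUN = seq_along)
  out <- cbind(data[1], idx = idx, data[-1])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a step/angle series written by [write_series_csv()]
#' @param path input path.
#' @export
read_series_csv <- function(path) {
  df <- read.csv(path, comment.char = "#")
  as_step_series(df)
}
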