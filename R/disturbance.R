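# Composite site-level human-disturbance index ------------------------------

#' Standardize one disturbance sub-index to a 0-10 scale
#'
#' Linear min-max rescale `((x - min)/(max - min)) * 10`, with the minimum
#' and maximum taken across all sampled sites. A constant sub-index carries
#' no signal and standardizes to 0 for every site (with a warning).
#'
#' @param x numeric vector of raw sub-index values.
#' @param min_x,max_x range over the sampled sites (defaults: observed
#'   range of `x`).
#' @return numeric vector in \[0, 10\].
#' @export
standardize_index <- function(x, min_x = min(x, na.rm = TRUE),
                              max_x = max(x, na.rm = TRUE)) {
  if (max_x == min_x) {
    warning("constant sub-index; standardized score set to 0 for all sites")
    return(rep(0, length(x)))
  }
  if (any(x < min_x | x > max_x, na.rm = TRUE)) {
    stop("values outside the supplied [min_x, max_x] range", call. = FALSE)
  }
  (x - min_x) / (max_x - min_x) * 10
}

#' Overall site-level disturbance index from eight standardized scores
#'
#' Sums the eight 0-10 scores and multiplies by 10/8, giving a possible
#' range of 0 to 100. A site missing any sub-index gets NA (the formula
#' presumes all eight values).
#'
#' @param scores numeric vector of 8 scores, or a matrix/data.frame with 8
#'   columns (one row per site).
#' @return numeric scalar or vector in \[0, 100\].
#' @export
overall_disturbance <- function(scores) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != 8) {
    stop("the overall index requires exactly eight sub-index scores",
         call. = FALSE)
  }
  if (any(scores < 0 | scores > 10, na.rm = TRUE)) {
    stop("standardized scores must lie in [0, 10]", call. = FALSE)
  }
  out <- rowSums(scores) * 10 / 8
  if (length(out) == 1 && is.null(rownames(scores))) out <- as.numeric(out)
  out
}

#' Score a disturbance table
#'
#' Standardizes each of the eight sub-indices across the sites of the table
#' (or against fixed reference ranges) and appends the overall 0-100
#' composite index.
#'
#' @param disturbance data.frame with columns `site_id`, `idx1..idx8`.
#' @param ranges optional 2 x 8 matrix (rows min, max) of fixed reference
#'   ranges for cross-dataset comparability; default is the observed
#'   per-index range.
#' @return the input with added columns `std_idx1..std_idx8` and `overall`.
#' @export
score_disturbance <- function(disturbance, ranges = NULL) {
  check_schema(disturbance, disturbance_schema, "disturbance")
  out <- disturbance
  cols <- paste0("idx", 1:8)
  for (j in seq_along(cols)) {
    x <- disturbance[[cols[j]]]
    if (is.null(ranges)) {
      out[[paste0("std_", cols[j])]] <- standardize_index(x)
    } else {
      out[[paste0("std_", cols[j])]] <-
        standardize_index(x, ranges[1, j], ranges[2, j])
    }
  }
  out$overall <- overall_disturbance(out[paste0("std_", cols)])
  out
}
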