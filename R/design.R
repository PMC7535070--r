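#' Create a one-dimensional design space
#'
#' A design space is a compact interval `[x_lo, x_hi]` of the controllable
#' variable (dose, concentration, time, ...).  All designs in this package
#' are probability measures on such an interval.
#'
#' @param x_lo,x_hi Finite interval endpoints with `x_lo < x_hi`.
#' @return An object of class `design_space`.
#' @export
design_space <- function(x_lo, x_hi) {
  stopifnot(is.numeric(x_lo), is.numeric(x_hi), length(x_lo) == 1L,
            length(x_hi) == 1L)
  if (!is.finite(x_lo) || !is.finite(x_hi))
    stop("design space must be bounded (both endpoints finite)")
  if (x_lo >= x_hi) stop("design space requires x_lo < x_hi")
  structure(list(x_lo = x_lo, x_hi = x_hi), class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat(sprintf("<design space [%g, %g]>\n", x$x_lo, x$x_hi))
  invisible(x)
}

#' Create an approximate design
#'
#' An approximate design is a discrete probability measure
#' `{s_1, ..., s_n; p_1, ..., p_n}`: support points `s_i` with weights `p_i`
#' giving the proportion of observations taken at each point.  Support points
#' are stored in increasing order; weights must be nonnegative and sum to 1
#' (they are renormalized when the deviation is a rounding artefact below
#' `2e-3`, as with designs printed to three decimals).
#'
#' @param support Numeric vector of support points.
#' @param weights Numeric vector of weights, or `NULL` for equal weights.
#' @return An object of class `design`.
#' @export
design <- function(support, weights = NULL) {
  support <- as.numeric(support)
  n <- length(support)
  if (n < 1L) stop("design needs at least one support point")
  if (is.null(weights)) weights <- rep(1 / n, n)
  weights <- as.numeric(weights)
  if (length(weights) != n)
    stop("support and weights must have equal length")
  if (any(!is.finite(support)) || any(!is.finite(weights)))
    stop("support and weights must be finite")
  if (any(weights < -1e-12)) stop("weights must be nonnegative")
  weights <- pmax(weights, 0)
  tot <- sum(weights)
  if (abs(tot - 1) > 2e-3)
    stop(sprintf("weights sum to %.8g, not 1", tot))
  weights <- weights / tot
  o <- order(support)
  structure(list(support = support[o], weights = weights[o]),
            class = "design")
}

#' @export
print.design <- function(x, digits = 6, ...) {
  cat("<design>\n")
  m <- rbind(support = signif(x$support, digits),
             weight  = signif(x$weights, digits))
  colnames(m) <- rep("", ncol(m))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.design <- function(x, ...) {
  data.frame(support = x$support, weight = x$weights)
}

#' Canonicalize a design
#'
#' Sorts the support, merges clusters of support points closer than
#' `merge_tol` times the design-space range (merged position is the
#' weight-averaged location, weights are summed), drops support points whose
#' weight falls below `weight_floor`, and renormalizes the weights.  Particle
#' swarm iterates drift support points arbitrarily close together; this
#' reduces them to the few distinct points a reported design actually has.
#' The operation is idempotent.
#'
#' @param d A [design].
#' @param space A [design_space]; used to scale `merge_tol`.
#' @param merge_tol Relative merge tolerance (fraction of the range).
#' @param weight_floor Weights below this are removed before renormalization.
#' @return A canonical [design].
#' @export
canonicalize <- function(d, space, merge_tol = 1e-3, weight_floor = 1e-3) {
  stopifnot(inherits(d, "design"), inherits(space, "design_space"))
  rng <- space$x_hi - space$x_lo
  s <- pmin(pmax(d$support, space$x_lo), space$x_hi)
  o <- order(s)
  s <- s[o]; w <- d$weights[o]
  gap <- merge_tol * rng
  # cluster consecutive points closer than gap
  cl <- cumsum(c(1, diff(s) > gap))
  ms <- tapply(s * w, cl, sum)
  mw <- tapply(w, cl, sum)
  pos <- ifelse(mw > 0, ms / mw, tapply(s, cl, mean))
  keep <- mw >= weight_floor
  if (!any(keep)) stop("degenerate design: all weights below floor")
  pos <- as.numeric(pos[keep]); mw <- as.numeric(mw[keep])
  design(pos, mw / sum(mw))
}

#' Serialize a design to JSON
#'
#' The JSON schema is `{"support": [...], "weights": [...]}` with 15
#' significant digits, so a round trip through [design_from_json] is
#' numerically stable.
#'
#' @param d A [design].
#' @param path Optional file to write to; if `NULL` the JSON string is
#'   returned.
#' @export
design_to_json <- function(d, path = NULL) {
  stopifnot(inherits(d, "design"))
  txt <- jsonlite::toJSON(list(support = d$support, weights = d$weights),
                          digits = I(15), auto_unbox = FALSE)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path)
  invisible(path)
}

#' @rdname design_to_json
#' @param txt JSON string or file path produced by [design_to_json].
#' @export
design_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  design(obj$support, obj$weights)
}

#' Read/write a design as two-column CSV
#'
#' Columns are `support` and `weight`.
#'
#' @param d A [design].
#' @param path File path.
#' @export
write_design_csv <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path)
  design(df$support, df$weight)
}
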