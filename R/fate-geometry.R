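#' Pure-fate segments in the feature plane
#'
#' After normalizing an (ancestor, duplicate, duplicate) expression triple
#' \eqn{(x, a, b)} by its maximum and mapping it to the feature plane
#' \eqn{(u, v) = (x - \max(a, b),\; x - \min(a, b))}, each pure evolutionary
#' fate corresponds to a closed line segment:
#' \describe{
#'   \item{SF}{\eqn{a + b = x}: the segment from (0, 1) to (0.5, 0.5) on the
#'     line \eqn{u + v = 1}.}
#'   \item{CF}{\eqn{a + b = 2x}: the segment from (-0.5, 0.5) to (0, 0) on the
#'     line \eqn{v = -u}.}
#'   \item{NF}{\eqn{x = a} with \eqn{x \le 0.5} (the gaining duplicate has at
#'     least twice the ancestral level): the segment from (-1, 0) to
#'     (-0.5, 0) on the line \eqn{v = 0}.}
#' }
#' All valid feature points satisfy \eqn{-1 \le u \le v \le 1} and lie in a
#' trapezoid whose corners (1, 1) and (-1, -1) are complete expression loss
#' and gain, respectively.
#'
#' @return A tibble with columns `fate`, `u0`, `v0`, `u1`, `v1` giving the two
#'   endpoints of each segment.
#' @seealso [classify_fate()], [plot_feature_plane()]
#' @export
#' @examples
#' fate_segments()
fate_segments <- function() {
  tibble::tibble(
    fate = c("SF", "CF", "NF"),
    u0 = c(0, -0.5, -1),
    v0 = c(1, 0.5, 0),
    u1 = c(0.5, 0, -0.5),
    v1 = c(0.5, 0, 0)
  )
}

#' Normalize an expression triple by its maximum
#'
#' Divides each of ancestor `x` and duplicates `a`, `b` by `max(x, a, b)`, so
#' the largest of the three equals 1 and fate classification becomes
#' scale-free. Vectorized over triples.
#'
#' @param x,a,b Nonnegative expression levels of the ancestor and the two
#'   duplicates (recycled to a common length).
#' @return A tibble with columns `x`, `a`, `b`, each in `[0, 1]` with
#'   rowwise maximum exactly 1.
#' @export
#' @examples
#' normalize_triple(70.3, 50, 50)
normalize_triple <- function(x, a, b) {
  chk <- vctrs_recycle3(x, a, b)
  x <- chk$x; a <- chk$a; b <- chk$b
  if (anyNA(x) || anyNA(a) || anyNA(b)) {
    stop("expression levels must not be NA", call. = FALSE)
  }
  if (any(x < 0 | a < 0 | b < 0)) {
    stop("expression levels must be nonnegative", call. = FALSE)
  }
  m <- pmax(x, a, b)
  if (any(m == 0)) {
    stop("unclassifiable triple: all three expression levels are zero",
         call. = FALSE)
  }
  tibble::tibble(x = x / m, a = a / m, b = b / m)
}

# recycle three vectors to a common length (scalar against vector only)
vctrs_recycle3 <- function(x, a, b) {
  n <- max(length(x), length(a), length(b))
  bad <- vapply(list(x, a, b), function(v) !(length(v) %in% c(1L, n)),
                logical(1))
  if (any(bad)) stop("x, a, b must have length 1 or a common length",
                     call. = FALSE)
  list(x = rep_len(as.numeric(x), n), a = rep_len(as.numeric(a), n),
       b = rep_len(as.numeric(b), n))
}

#' Map a normalized triple to the feature plane
#'
#' Computes \eqn{u = x - \max(a, b)} and \eqn{v = x - \min(a, b)}. Because
#' `max(x, a, b) = 1`, the pair `(u, v)` retains all information in the
#' normalized triple, and is invariant to swapping the two duplicates.
#'
#' @param x,a,b Components of a normalized triple (see [normalize_triple()]).
#' @return A tibble with columns `u` and `v`, satisfying `-1 <= u <= v <= 1`.
#' @export
#' @examples
#' to_feature_point(1, 0.71124, 0.71124)
to_feature_point <- function(x, a, b) {
  chk <- vctrs_recycle3(x, a, b)
  tibble::tibble(u = chk$x - pmax(chk$a, chk$b),
                 v = chk$x - pmin(chk$a, chk$b))
}

#' Euclidean distance from points to a closed segment
#'
#' Distance to the closed segment with endpoints `(u0, v0)` and `(u1, v1)`:
#' the perpendicular distance when the foot of the perpendicular falls inside
#' the segment, otherwise the distance to the nearer endpoint.
#'
#' @param u,v Point coordinates (vectorized).
#' @param u0,v0,u1,v1 Segment endpoints (scalars).
#' @return Numeric vector of nonnegative distances; 0 iff the point lies on
#'   the closed segment.
#' @export
#' @examples
#' point_segment_distance(0.28876, 0.28876, 0, 1, 0.5, 0.5)
point_segment_distance <- function(u, v, u0, v0, u1, v1) {
  du <- u1 - u0
  dv <- v1 - v0
  len2 <- du * du + dv * dv
  if (len2 == 0) stop("degenerate segment", call. = FALSE)
  t <- pmin(1, pmax(0, ((u - u0) * du + (v - v0) * dv) / len2))
  sqrt((u - (u0 + t * du))^2 + (v - (v0 + t * dv))^2)
}

#' Classify a duplication event as SF, CF or NF
#'
#' Normalizes the (ancestor, duplicate, duplicate) triple, maps it to the
#' feature plane, computes Euclidean distances \eqn{d_{SF}, d_{CF}, d_{NF}}
#' to the three pure-fate segments ([fate_segments()]), and converts the
#' distances to fate probabilities:
#' \deqn{p_{SF} = \frac{d_{CF} d_{NF}}{d_{CF} d_{NF} + d_{SF} d_{NF} + d_{CF} d_{SF}}}
#' and analogously for CF and NF, so that the three probabilities sum to 1
#' and a fate whose segment contains the point receives probability 1 (the
#' continuous limit when exactly one distance is zero; the segments are
#' pairwise disjoint so two distances cannot vanish together).
#'
#' Points within Euclidean distance 0.05 of the trapezoid corners (1, 1)
#' (complete expression loss, the extreme of SF) or (-1, -1) (complete
#' expression gain, the extreme of NF) are flagged in `near_corner`; they are
#' still classified.
#'
#' @param x,a,b Nonnegative expression levels of ancestor and duplicates
#'   (vectorized; recycled to a common length).
#' @param on_zero What to do with all-zero triples: `"error"` (default) or
#'   `"na"` to return a row of `NA`s flagged `unclassifiable = TRUE`.
#' @return A tibble with one row per triple: feature-plane coordinates
#'   `u`, `v`; distances `d_sf`, `d_cf`, `d_nf`; probabilities `p_sf`,
#'   `p_cf`, `p_nf`; `label` (argmax fate); `confidence` (max probability);
#'   `near_corner`; `unclassifiable`.
#' @export
#' @examples
#' classify_fate(70.3, 50, 50)    # SF most probable (0.48)
#' classify_fate(76.5, 70.3, 200) # NF most probable (0.91)
classify_fate <- function(x, a, b, on_zero = c("error", "na")) {
  on_zero <- match.arg(on_zero)
  chk <- vctrs_recycle3(x, a, b)
  x <- chk$x; a <- chk$a; b <- chk$b
  if (any(x < 0 | a < 0 | b < 0, na.rm = TRUE)) {
    stop("expression levels must be nonnegative", call. = FALSE)
  }
  m <- pmax(x, a, b)
  zero <- is.na(m) | m == 0
  if (any(zero) && on_zero == "error") {
    stop("unclassifiable triple: all three expression levels are zero",
         call. = FALSE)
  }
  m[zero] <- 1 # placeholder; rows overwritten with NA below
  u <- x / m - pmax(a, b) / m
  v <- x / m - pmin(a, b) / m
  segs <- fate_segments()
  d <- vapply(seq_len(3L), function(i) {
    point_segment_distance(u, v, segs$u0[i], segs$v0[i], segs$u1[i], segs$v1[i])
  }, numeric(length(u)))
  d <- matrix(d, ncol = 3L,
              dimnames = list(NULL, c("d_sf", "d_cf", "d_nf")))
  pr <- cbind(sf = d[, "d_cf"] * d[, "d_nf"],
              cf = d[, "d_sf"] * d[, "d_nf"],
              nf = d[, "d_sf"] * d[, "d_cf"])
  # continuous limit of the distance-product formula: on-segment points get 1
  on_seg <- d == 0
  hit <- rowSums(on_seg) > 0
  pr[hit, ] <- (on_seg * 1)[hit, , drop = FALSE]
  pr <- pr / rowSums(pr)
  lab <- c("SF", "CF", "NF")[max.col(pr, ties.method = "first")]
  conf <- pmax(pr[, 1], pr[, 2], pr[, 3])
  near_corner <- sqrt((u - 1)^2 + (v - 1)^2) <= 0.05 |
    sqrt((u + 1)^2 + (v + 1)^2) <= 0.05
  out <- tibble::tibble(
    u = u, v = v,
    d_sf = d[, "d_sf"], d_cf = d[, "d_cf"], d_nf = d[, "d_nf"],
    p_sf = pr[, 1], p_cf = pr[, 2], p_nf = pr[, 3],
    label = lab, confidence = conf,
    near_corner = near_corner,
    unclassifiable = zero
  )
  if (any(zero)) {
    out[zero, setdiff(names(out), "unclassifiable")] <- NA
  }
  out
}

#' Classify fates for a data frame of triples
#'
#' Data-frame-first wrapper around [classify_fate()]: expects columns `x`,
#' `a`, `b` and returns the input with the classification columns appended,
#' so it composes with the pipe.
#'
#' @param data A data frame with numeric columns `x`, `a`, `b`.
#' @inheritParams classify_fate
#' @return `data` as a tibble with the columns of [classify_fate()] appended.
#' @export
#' @examples
#' tibble::tibble(x = c(100, 100), a = c(50, 100), b = c(50, 200)) |>
#'   classify_fates()
classify_fates <- function(data, on_zero = c("error", "na")) {
  stopifnot(is.data.frame(data), all(c("x", "a", "b") %in% names(data)))
  dplyr::bind_cols(tibble::as_tibble(data),
                   classify_fate(data$x, data$a, data$b, on_zero = on_zero))
}
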