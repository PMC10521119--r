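#' Local extrema of an amplitude map
#'
#' Finds all strict local maxima (or minima) over the 8-connected
#' neighborhood inside the valid region of the map. Connected plateaus of
#' equal value whose entire border lies strictly below (above) the plateau are
#' reduced to their centroid. Results are sorted by amplitude -- descending
#' for maxima, ascending for minima -- with ties broken in row-major scan
#' order (top-left first). A constant map has no strict extrema and yields an
#' empty result.
#'
#' Coordinates are in pixels: `x` is the column, `y` the row, origin at the
#' top-left; plateau centroids may be fractional.
#'
#' @param map an `amplitude_map`, or a plain numeric matrix (then `margin`
#'   applies).
#' @param polarity `"max"` or `"min"`.
#' @param margin border excluded from the search when `map` is a matrix
#'   (default 0).
#' @return A tibble with columns `x`, `y`, `amplitude`.
#' @export
local_extrema <- function(map, polarity = c("max", "min"), margin = 0) {
  polarity <- match.arg(polarity)
  v <- if (inherits(map, "amplitude_map")) map$values else map
  mrg <- if (inherits(map, "amplitude_map")) map$valid_margin_px else margin
  stopifnot(is.matrix(v))
  sgn <- if (polarity == "max") 1 else -1
  w <- sgn * v
  s_r <- nrow(w); s_c <- ncol(w)
  if (s_r - 2 * mrg <= 0 || s_c - 2 * mrg <= 0) {
    stop("valid region is empty for this margin", call. = FALSE)
  }
  nb <- neighbor_max(w)
  valid <- matrix(FALSE, s_r, s_c)
  valid[(mrg + 1):(s_r - mrg), (mrg + 1):(s_c - mrg)] <- TRUE
  cand <- valid & (w >= nb)
  strict <- cand & (w > nb)
  out_x <- numeric(0); out_y <- numeric(0); out_a <- numeric(0)
  # strict single-pixel extrema
  if (any(strict)) {
    idx <- which(strict, arr.ind = TRUE)
    out_y <- as.numeric(idx[, 1]); out_x <- as.numeric(idx[, 2])
    out_a <- w[strict]
  }
  # plateau candidates: equal to the neighborhood maximum somewhere
  plateau <- cand & !strict
  if (any(plateau)) {
    seen <- matrix(FALSE, s_r, s_c)
    seeds <- which(plateau, arr.ind = TRUE)
    for (i in seq_len(nrow(seeds))) {
      r0 <- seeds[i, 1]; c0 <- seeds[i, 2]
      if (seen[r0, c0]) next
      comp <- flood_equal(w, r0, c0)
      seen[comp] <- TRUE
      val <- w[r0, c0]
      if (plateau_is_extremum(w, comp, val)) {
        ij <- which(comp, arr.ind = TRUE)
        cy <- mean(ij[, 1]); cx <- mean(ij[, 2])
        # centroid must fall in the valid region
        if (cy > mrg && cy <= s_r - mrg && cx > mrg && cx <= s_c - mrg) {
          out_y <- c(out_y, cy); out_x <- c(out_x, cx); out_a <- c(out_a, val)
        }
      }
    }
  }
  if (length(out_a) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), amplitude = numeric(0)))
  }
  amp <- sgn * out_a
  ord <- order(-out_a, out_y, out_x) # by extremity, then row-major
  tibble::tibble(x = out_x[ord], y = out_y[ord], amplitude = amp[ord])
}

# maximum over the 8 neighbors, borders treated as -Inf
neighbor_max <- function(w) {
  s_r <- nrow(w); s_c <- ncol(w)
  shift <- function(dr, dc) {
    out <- matrix(-Inf, s_r, s_c)
    rs <- max(1, 1 + dr):min(s_r, s_r + dr)
    cs <- max(1, 1 + dc):min(s_c, s_c + dc)
    out[rs, cs] <- w[rs - dr, cs - dc]
    out
  }
  nb <- shift(1, 0)
  for (d in list(c(-1, 0), c(0, 1), c(0, -1), c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    nb <- pmax(nb, shift(d[1], d[2]))
  }
  nb
}

# 8-connected flood fill over pixels equal to w[r0, c0]; returns logical mask
flood_equal <- function(w, r0, c0) {
  s_r <- nrow(w); s_c <- ncol(w)
  val <- w[r0, c0]
  comp <- matrix(FALSE, s_r, s_c)
  stack <- matrix(c(r0, c0), ncol = 2)
  comp[r0, c0] <- TRUE
  while (nrow(stack) > 0) {
    r <- stack[nrow(stack), 1]; c <- stack[nrow(stack), 2]
    stack <- stack[-nrow(stack), , drop = FALSE]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= s_r && cc >= 1 && cc <= s_c &&
          !comp[rr, cc] && w[rr, cc] == val) {
        comp[rr, cc] <- TRUE
        stack <- rbind(stack, c(rr, cc))
      }
    }
  }
  comp
}

# TRUE if every pixel bordering the component lies strictly below `val`
plateau_is_extremum <- function(w, comp, val) {
  ij <- which(comp, arr.ind = TRUE)
  s_r <- nrow(w); s_c <- ncol(w)
  has_border <- FALSE
  for (i in seq_len(nrow(ij))) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- ij[i, 1] + dr; cc <- ij[i, 2] + dc
      if (rr < 1 || rr > s_r || cc < 1 || cc > s_c) next
      if (!comp[rr, cc]) {
        has_border <- TRUE
        if (w[rr, cc] >= val) return(FALSE)
      }
    }
  }
  has_border
}

#' Select non-overlapping extrema
#'
#' Greedy selection of `n` extrema in extremity order, skipping any candidate
#' closer than `min_sep` (Euclidean center distance) to an already accepted
#' point; with `min_sep = d_px` the selected windows may touch but not
#' overlap. If the map does not contain `n` sufficiently separated extrema, a
#' warning is emitted and the shorter set returned.
#'
#' @inheritParams local_extrema
#' @param n number of points to select; defaults to the scale's `n_windows`.
#' @param min_sep minimum pairwise center distance in px; defaults to the
#'   scale's center diameter.
#' @return An `extrema_set`: a tibble `x`, `y`, `amplitude` with attributes
#'   `kind` (`"max"`/`"min"`), `scale`, `min_sep`.
#' @export
select_extrema <- function(map, polarity = c("max", "min"), n = NULL,
                           min_sep = NULL, margin = 0) {
  polarity <- match.arg(polarity)
  scale <- if (inherits(map, "amplitude_map")) map$scale else NULL
  if (is.null(n)) {
    if (is.null(scale)) stop("`n` must be given for a plain matrix", call. = FALSE)
    n <- scale$n_windows
  }
  if (is.null(min_sep)) {
    if (is.null(scale)) stop("`min_sep` must be given for a plain matrix", call. = FALSE)
    min_sep <- scale$d_px
  }
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  cand <- local_extrema(map, polarity, margin = margin)
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep) >= n) break
    if (all(sqrt((cand$x[keep] - cand$x[i])^2 +
                 (cand$y[keep] - cand$y[i])^2) >= min_sep)) {
      keep <- c(keep, i)
    }
  }
  if (length(keep) < n) {
    warning(sprintf(
      "map yields only %d of the requested %d separated %sima",
      length(keep), n, polarity
    ), call. = FALSE)
  }
  new_extrema_set(cand[keep, ], kind = polarity, scale = scale, min_sep = min_sep)
}

new_extrema_set <- function(df, kind, scale, min_sep) {
  structure(
    tibble::as_tibble(df),
    kind = kind, scale = scale, min_sep = min_sep,
    class = c("extrema_set", class(tibble::tibble()))
  )
}

#' Select medium-amplitude points between paired extrema
#'
#' For each rank `j`, the target amplitude is the midpoint
#' `(A_max[j] + A_min[j]) / 2` of the `j`-th selected maximum and minimum
#' (amplitude-rank pairing). The chosen point is the valid-region pixel whose
#' map value is nearest the target, subject to the same minimum-separation
#' constraint among the chosen medium points; ties are broken in row-major
#' order.
#'
#' @inheritParams local_extrema
#' @param maxima,minima `extrema_set`s from [select_extrema()] on the same map.
#' @param min_sep minimum pairwise distance among medium points; defaults to
#'   the separation recorded in `maxima`.
#' @return An `extrema_set` of kind `"med"` with an extra `target` column.
#' @export
select_medium <- function(map, maxima, minima, min_sep = NULL, margin = 0) {
  if (nrow(maxima) == 0 || nrow(minima) == 0) {
    stop("`maxima` and `minima` must be non-empty", call. = FALSE)
  }
  v <- if (inherits(map, "amplitude_map")) map$values else map
  mrg <- if (inherits(map, "amplitude_map")) map$valid_margin_px else margin
  scale <- if (inherits(map, "amplitude_map")) map$scale else attr(maxima, "scale")
  if (is.null(min_sep)) min_sep <- attr(maxima, "min_sep")
  n <- min(nrow(maxima), nrow(minima))
  targets <- (maxima$amplitude[seq_len(n)] + minima$amplitude[seq_len(n)]) / 2
  s_r <- nrow(v); s_c <- ncol(v)
  rows <- (mrg + 1):(s_r - mrg); cols <- (mrg + 1):(s_c - mrg)
  # row-major candidate order: top-left first
  grid <- expand.grid(x = cols, y = rows)[, c("x", "y")]
  grid <- grid[order(grid$y, grid$x), ]
  amps <- v[cbind(grid$y, grid$x)]
  sel_x <- numeric(0); sel_y <- numeric(0); sel_a <- numeric(0)
  for (t in targets) {
    ord <- order(abs(amps - t), seq_along(amps)) # row-major on ties
    for (i in ord) {
      if (all(sqrt((sel_x - grid$x[i])^2 + (sel_y - grid$y[i])^2) >= min_sep)) {
        sel_x <- c(sel_x, grid$x[i]); sel_y <- c(sel_y, grid$y[i])
        sel_a <- c(sel_a, amps[i])
        break
      }
    }
  }
  if (length(sel_a) < n) {
    warning("could not place all medium points at the required separation",
            call. = FALSE)
  }
  df <- tibble::tibble(x = sel_x, y = sel_y, amplitude = sel_a,
                       target = targets[seq_along(sel_a)])
  new_extrema_set(df, kind = "med", scale = scale, min_sep = min_sep)
}

#' @export
print.extrema_set <- function(x, ...) {
  cat(sprintf("<extrema_set> kind=%s, %d points (min_sep %g px)\n",
              attr(x, "kind"), nrow(x), attr(x, "min_sep")))
  NextMethod()
}

#' Serialize extrema sets to JSON
#'
#' @param sets an `extrema_set` or list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_extrema <- function(sets, path) {
  if (inherits(sets, "extrema_set")) sets <- list(sets)
  payload <- purrr::map(sets, function(s) {
    list(
      kind = attr(s, "kind"),
      min_sep = attr(s, "min_sep"),
      scale = if (!is.null(attr(s, "scale"))) as.list(attr(s, "scale")),
      points = as.data.frame(s)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
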