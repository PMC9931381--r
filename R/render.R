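# Template rectangles (row/col extents on the 16 x 28 default grid) for the
# seven areas: fingers II-V along the top band, thumb opposing them, thenar
# and hypothenar in the palm band. Disjoint by construction at scale 1.
.area_templates <- function() {
  list(II = list(rows = c(1, 6),  cols = c(1, 5)),
       III = list(rows = c(1, 6),  cols = c(7, 11)),
       IV = list(rows = c(1, 6),  cols = c(13, 17)),
       V = list(rows = c(1, 6),  cols = c(19, 23)),
       I = list(rows = c(4, 9),  cols = c(25, 28)),
       TH = list(rows = c(9, 16), cols = c(1, 6)),
       HY = list(rows = c(9, 16), cols = c(8, 13)))
}

# Scale a rectangle about its centre, clamped to the grid.
.scale_rect <- function(rect, scale, nr, nc) {
  mid_r <- mean(rect$rows); mid_c <- mean(rect$cols)
  hr <- (rect$rows[2] - rect$rows[1] + 1) * scale / 2
  hc <- (rect$cols[2] - rect$cols[1] + 1) * scale / 2
  r <- c(ceiling(mid_r - hr), floor(mid_r + hr - 1e-9))
  c <- c(ceiling(mid_c - hc), floor(mid_c + hc - 1e-9))
  if (r[1] < 1 || c[1] < 1 || r[2] > nr || c[2] > nc)
    stop("hand_scale too large: area template exceeds the sensor grid")
  if (r[2] < r[1] || c[2] < c[1])
    stop("hand_scale too small to place 7 disjoint area templates")
  list(rows = r, cols = c)
}

#' Render an area-load record as a synthetic sensor grid plus mask
#'
#' Draws one plausible pressure image of a grip with the given load
#' distribution: seven disjoint area templates on a 16 x 28 sensor grid
#' (2 sensors per cm2 on a 200 mm cylinder patch) receive smooth Gaussian
#' force blobs whose per-area sums equal the requested area forces exactly,
#' so `aggregate_map(grid, mask)` recovers the input percents and total
#' force up to floating-point error. A random 60-80% of each template's
#' cells is activated, which at the default `hand_scale` keeps the number
#' of loaded sensors in the 120-200 range typical of cylinder grips.
#'
#' @param loads An [area_loads()] object with positive total force.
#' @param hand_scale Multiplicative scale applied to every area template
#'   (default 1). Values too small to place seven disjoint templates, or so
#'   large that templates overlap or leave the grid, raise an error.
#' @param seed Optional integer seed.
#' @return A list with elements `grid` ([sensor_grid()]) and `mask`
#'   ([area_mask()]).
#' @export
#' @examples
#' l <- area_loads(300, c(I = 20, II = 12, III = 16, IV = 13, V = 8,
#'                        TH = 16, HY = 15))
#' rm <- render_map(l, seed = 1)
#' aggregate_map(rm$grid, rm$mask)
render_map <- function(loads, hand_scale = 1, seed = NULL) {
  stopifnot(inherits(loads, "area_loads"), loads$total_force > 0,
            hand_scale > 0)
  if (!is.null(seed)) set.seed(seed)
  nr <- 16L; nc <- 28L
  tmpl <- lapply(.area_templates(), .scale_rect, scale = hand_scale,
                 nr = nr, nc = nc)
  assignment <- matrix(NA_character_, nr, nc)
  for (code in names(tmpl)) {
    rect <- tmpl[[code]]
    cells <- assignment[rect$rows[1]:rect$rows[2], rect$cols[1]:rect$cols[2]]
    if (any(!is.na(cells)))
      stop("hand_scale too large: area templates overlap")
    assignment[rect$rows[1]:rect$rows[2],
               rect$cols[1]:rect$cols[2]] <- code
  }
  values <- matrix(0, nr, nc)
  for (code in hand_areas()) {
    force_a <- loads$total_force * loads$percent[[code]] / 100
    if (force_a <= 0) next
    rect <- tmpl[[code]]
    rs <- rect$rows[1]:rect$rows[2]; cs <- rect$cols[1]:rect$cols[2]
    cells <- expand.grid(r = rs, c = cs)
    n_cells <- nrow(cells)
    # smooth blob: Gaussian of distance from a jittered centre, with mild
    # multiplicative texture
    ctr_r <- mean(rs) + stats::runif(1, -0.5, 0.5)
    ctr_c <- mean(cs) + stats::runif(1, -0.5, 0.5)
    sig_r <- max(0.8, (length(rs)) / 2.5)
    sig_c <- max(0.8, (length(cs)) / 2.5)
    w <- exp(-((cells$r - ctr_r)^2 / (2 * sig_r^2) +
               (cells$c - ctr_c)^2 / (2 * sig_c^2)))
    w <- w * exp(stats::rnorm(n_cells, 0, 0.2))
    k <- max(1L, round(stats::runif(1, 0.6, 0.8) * n_cells))
    active <- order(w, decreasing = TRUE)[seq_len(k)]
    wa <- w[active]
    values[cbind(cells$r[active], cells$c[active])] <-
      force_a * wa / sum(wa)
  }
  list(grid = sensor_grid(values), mask = area_mask(assignment))
}
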