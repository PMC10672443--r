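#' Clinical decision thresholds for the temperature error grid
#'
#' Under active underbody warming at a 26 C room temperature, only core
#' temperatures below `hypo_c` (hypothermia) or above `hyper_c`
#' (hyperthermia) trigger additional treatment; `tolerance_c` is the
#' clinically irrelevant measurement-error band.
#'
#' @param tolerance_c acceptable absolute error in degrees C (default 0.5,
#'   inclusive).
#' @param hypo_c hypothermia treatment threshold (default 35.6; strictly
#'   below triggers warming).
#' @param hyper_c hyperthermia treatment threshold (default 37.9; strictly
#'   above triggers cooling).
#' @return An object of class `grid_thresholds`.
#' @export
grid_thresholds <- function(tolerance_c = 0.5, hypo_c = 35.6, hyper_c = 37.9) {
  stopifnot(tolerance_c > 0, hypo_c < hyper_c)
  structure(list(tolerance_c = tolerance_c, hypo_c = hypo_c,
                 hyper_c = hyper_c), class = "grid_thresholds")
}

ZONE_LEVELS <- c("A", "B", "C", "D", "E")

#' Treatment decision implied by a temperature
#'
#' `"WARM"` strictly below the hypothermia threshold, `"COOL"` strictly
#' above the hyperthermia threshold, otherwise `"NONE"` (both boundary
#' values themselves imply no treatment).
#'
#' @param t temperature(s) in degrees C.
#' @param thr a [grid_thresholds()].
#' @return Character vector in `{"WARM", "NONE", "COOL"}`.
#' @export
temp_decision <- function(t, thr = grid_thresholds()) {
  ifelse(t < thr$hypo_c, "WARM", ifelse(t > thr$hyper_c, "COOL", "NONE"))
}

#' Classify paired measurements into error-grid zones A-E
#'
#' Zone A: absolute error within the tolerance (clinically irrelevant; takes
#' precedence even when the pair straddles a treatment threshold).
#' Zone E: the two temperatures imply opposite treatments.
#' Zone C: the reference implies no treatment but the test device triggers
#' one (unnecessary treatment).
#' Zone D: the reference implies treatment but the test device does not
#' (failure to detect the need for treatment).
#' Zone B: error beyond the tolerance but the same decision either way.
#'
#' @param t_rec reference (rectal) temperature(s), degrees C.
#' @param t_dhf test-device temperature(s), degrees C.
#' @param thr a [grid_thresholds()].
#' @param a_precedence if `FALSE`, pairs inside the tolerance band whose
#'   decisions differ are classified by decision (C/D) instead of A.
#' @return Factor with levels `A`-`E`, one label per pair.
#' @export
classify_zone <- function(t_rec, t_dhf, thr = grid_thresholds(),
                          a_precedence = TRUE) {
  stopifnot(length(t_rec) == length(t_dhf))
  dec_r <- temp_decision(t_rec, thr)
  dec_d <- temp_decision(t_dhf, thr)
  in_band <- abs(t_dhf - t_rec) <= thr$tolerance_c
  opposite <- (dec_r == "WARM" & dec_d == "COOL") |
              (dec_r == "COOL" & dec_d == "WARM")
  unnecessary <- dec_r == "NONE" & dec_d != "NONE"
  missed <- dec_r != "NONE" & dec_d == "NONE"
  zone <- rep("B", length(t_rec))
  zone[opposite] <- "E"
  zone[unnecessary] <- "C"
  zone[missed] <- "D"
  if (a_precedence) zone[in_band] <- "A" else zone[in_band & !opposite &
                                                  !unnecessary & !missed] <- "A"
  factor(zone, levels = ZONE_LEVELS)
}

#' Summarize error-grid zones over a cohort
#'
#' @param pairs paired-observation data frame with `t_rec`, `t_dhf`.
#' @param thr a [grid_thresholds()].
#' @param a_precedence see [classify_zone()].
#' @return An object of class `grid_summary`: `counts` and `percentages`
#'   (named by zone, full precision), `n_pairs`, `zone` (per-pair labels)
#'   and `percent_no_wrong_decision` (zones A plus B: measurements that do
#'   not change clinical management).
#' @export
summarize_grid <- function(pairs, thr = grid_thresholds(),
                           a_precedence = TRUE) {
  stopifnot(nrow(pairs) > 0)
  zone <- classify_zone(pairs$t_rec, pairs$t_dhf, thr, a_precedence)
  counts <- table(zone)
  pct <- 100 * as.numeric(counts) / nrow(pairs)
  names(pct) <- names(counts)
  structure(list(counts = counts, percentages = pct,
                 n_pairs = nrow(pairs),
                 percent_no_wrong_decision = pct[["A"]] + pct[["B"]],
                 zone = zone, thresholds = thr),
            class = "grid_summary")
}

#' @export
print.grid_summary <- function(x, ...) {
  cat("Temperature error-grid summary (", x$n_pairs, " pairs)\n", sep = "")
  lab <- c(A = "acceptable error",
           B = "error without clinical impact",
           C = "unnecessary treatment",
           D = "failure to detect need for treatment",
           E = "opposite of correct treatment")
  for (z in ZONE_LEVELS) {
    cat(sprintf("  Zone %s: %5d  (%6.2f%%)  %s\n", z, x$counts[[z]],
                x$percentages[[z]], lab[[z]]))
  }
  cat(sprintf("  No wrong clinical decision (A+B): %.2f%%\n",
              x$percent_no_wrong_decision))
  invisible(x)
}

# clip a convex polygon (matrix with columns x, y) by halfplane a*x+b*y <= c
clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (!n) return(poly)
  keep <- a * poly[, 1] + b * poly[, 2] <= cc + 1e-12
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    p <- poly[i, ]; q <- poly[j, ]
    if (keep[i]) out <- rbind(out, p)
    if (xor(keep[i], keep[j])) {
      denom <- a * (q[1] - p[1]) + b * (q[2] - p[2])
      t <- (cc - a * p[1] - b * p[2]) / denom
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

#' Error-grid zone geometry
#'
#' Partitions the (reference, test) plane into the zone regions implied by
#' [classify_zone()]: the plane is cut into 3 x 3 decision blocks by the two
#' treatment thresholds on each axis, and each block into the parts inside,
#' above and below the diagonal tolerance band. Every piece carries both a
#' convex vertex polygon (for plotting) and its defining inequalities (for
#' point lookup), so membership and the pointwise classifier can be
#' cross-checked exhaustively.
#'
#' @param thr a [grid_thresholds()].
#' @param axis_range numeric length-2: common axis range in degrees C; must
#'   cover both thresholds.
#' @param a_precedence see [classify_zone()].
#' @return An object of class `error_grid_geometry` with `pieces` (a data
#'   frame of constraints `xlo`, `xhi`, `ylo`, `yhi`, `band`, `zone`) and
#'   `polygons` (data frame of vertices `x`, `y` with `piece` and `zone`).
#' @export
grid_geometry <- function(thr = grid_thresholds(), axis_range = c(33, 40),
                          a_precedence = TRUE) {
  stopifnot(length(axis_range) == 2)
  lo <- axis_range[1]; hi <- axis_range[2]
  if (!(lo < hi)) stop("degenerate axis range", call. = FALSE)
  if (lo >= thr$hypo_c || hi <= thr$hyper_c) {
    stop("axis range must cover both treatment thresholds", call. = FALSE)
  }
  cuts <- c(lo, thr$hypo_c, thr$hyper_c, hi)
  dec_lab <- c("WARM", "NONE", "COOL")
  zone_of <- function(dr, dd, band) {
    if (band == "inside" && a_precedence) return("A")
    opposite <- (dr == "WARM" && dd == "COOL") || (dr == "COOL" && dd == "WARM")
    if (opposite) return("E")
    if (dr == "NONE" && dd != "NONE") return("C")
    if (dr != "NONE" && dd == "NONE") return("D")
    if (band == "inside") "A" else "B"
  }
  pieces <- list(); polys <- list(); k <- 0L
  tol <- thr$tolerance_c
  for (ix in 1:3) for (iy in 1:3) {
    rect <- cbind(x = c(cuts[ix], cuts[ix + 1], cuts[ix + 1], cuts[ix]),
                  y = c(cuts[iy], cuts[iy], cuts[iy + 1], cuts[iy + 1]))
    for (band in c("inside", "above", "below")) {
      # x is t_rec, y is t_dhf; band constraints on y - x
      p <- rect
      if (band == "inside") {
        p <- clip_halfplane(p, -1, 1, tol)    #  y - x <= tol
        p <- clip_halfplane(p, 1, -1, tol)    # -(y - x) <= tol
      } else if (band == "above") {
        p <- clip_halfplane(p, 1, -1, -tol)   # y - x >= tol
      } else {
        p <- clip_halfplane(p, -1, 1, -tol)   # y - x <= -tol
      }
      if (polygon_area(p) < 1e-9) next
      k <- k + 1L
      zone <- zone_of(dec_lab[ix], dec_lab[iy], band)
      pieces[[k]] <- data.frame(piece = k, xlo = cuts[ix], xhi = cuts[ix + 1],
                                ylo = cuts[iy], yhi = cuts[iy + 1],
                                xblock = ix, yblock = iy,
                                band = band, zone = zone,
                                stringsAsFactors = FALSE)
      polys[[k]] <- data.frame(piece = k, zone = zone,
                               x = p[, 1], y = p[, 2])
    }
  }
  structure(list(pieces = do.call(rbind, pieces),
                 polygons = do.call(rbind, polys),
                 thresholds = thr, axis_range = axis_range,
                 a_precedence = a_precedence),
            class = "error_grid_geometry")
}

#' Look up zones from grid geometry
#'
#' Classifies points by evaluating each geometry piece's defining
#' inequalities (decision-block membership with the same strict/inclusive
#' conventions as [temp_decision()], and the tolerance-band side). This is an
#' independent route to the same partition as [classify_zone()] and is used
#' to validate the geometry.
#'
#' @param geom an [grid_geometry()] object.
#' @param t_rec,t_dhf coordinates to classify.
#' @return Factor of zone labels (NA outside the axis range).
#' @export
geometry_classify <- function(geom, t_rec, t_dhf) {
  stopifnot(inherits(geom, "error_grid_geometry"),
            length(t_rec) == length(t_dhf))
  thr <- geom$thresholds
  # decision-block index along one axis: 1 strictly below hypo, 3 strictly
  # above hyper, 2 in the closed middle band
  block <- function(t) 1L + (t >= thr$hypo_c) + (t > thr$hyper_c)
  bx <- block(t_rec); by <- block(t_dhf)
  delta <- t_dhf - t_rec
  band <- ifelse(abs(delta) <= thr$tolerance_c, "inside",
                 ifelse(delta > thr$tolerance_c, "above", "below"))
  key <- paste(bx, by, band)
  pk <- paste(geom$pieces$xblock, geom$pieces$yblock, geom$pieces$band)
  zone <- geom$pieces$zone[match(key, pk)]
  inside <- t_rec >= geom$axis_range[1] & t_rec <= geom$axis_range[2] &
            t_dhf >= geom$axis_range[1] & t_dhf <= geom$axis_range[2]
  zone[!inside] <- NA
  factor(zone, levels = ZONE_LEVELS)
}

#' Plot the clinical error grid
#'
#' Draws the zone polygons over the (reference, test) plane, optionally with
#' a scatter overlay of observed pairs.
#'
#' @param x an [grid_geometry()] object.
#' @param pairs optional paired-observation data frame to overlay.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.error_grid_geometry <- function(x, pairs = NULL, ...) {
  rng <- x$axis_range
  cols <- c(A = "#d9f0d3", B = "#fee08b", C = "#fdae61", D = "#f46d43",
            E = "#d73027")
  graphics::plot(NA, xlim = rng, ylim = rng, xlab = "Reference temperature (C)",
                 ylab = "DHF temperature (C)", asp = 1, ...)
  for (k in unique(x$polygons$piece)) {
    pp <- x$polygons[x$polygons$piece == k, ]
    graphics::polygon(pp$x, pp$y, col = cols[[pp$zone[1]]], border = "white")
    cx <- mean(range(pp$x)); cy <- mean(range(pp$y))
    graphics::text(cx, cy, pp$zone[1], cex = 0.7, col = "grey30")
  }
  if (!is.null(pairs)) {
    graphics::points(pairs$t_rec, pairs$t_dhf, pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("black", 0.4))
  }
  invisible(x)
}
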