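# Stable per-compound seed offset so that, inside a multi-compound summary,
# each compound gets independent (but reproducible) error draws.
.compound_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) + h) %% .Machine$integer.max
}

#' Gaussian input-error scenarios for a compound
#'
#' Scenario 0 is the original compound; scenarios 1..n replace Vss and Cl
#' by independent draws `10^N(log10(original), sd)` on the log10 scale,
#' leaving every other field unchanged.  A draw that makes the model
#' degenerate is redrawn (and counted): clearance at or above liver blood
#' flow (first-pass fraction would be <= 0), or a whole-body Vss at or
#' below 3.0 L (the plasma-volume distribution scenarios would have
#' V_central >= V_ss).
#'
#' @param compound A [compound()].
#' @param settings A [model_settings()]; supplies `error_sd_log10` and
#'   `n_error_scenarios`.
#' @param seed Integer seed for the draws.
#' @return A list of `n_error_scenarios + 1` `compound` objects (the first
#'   being the original), with a `redraws` attribute counting rejected
#'   draws.
#' @export
make_error_scenarios <- function(compound, settings = model_settings(),
                                 seed = settings$rng_seed) {
  n <- settings$n_error_scenarios
  sd <- settings$error_sd_log10
  bw <- settings$body_weight
  redraws <- 0L
  draw_valid <- function(orig, valid) {
    repeat {
      # multiplicative form of 10^N(log10(orig), sd); exact at sd = 0
      x <- orig * 10^stats::rnorm(1, mean = 0, sd = sd)
      if (valid(x)) return(x)
      redraws <<- redraws + 1L
    }
  }
  perturbed <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cp <- compound
      cp$vss_per_kg <- draw_valid(compound$vss_per_kg,
                                  function(v) v * bw > 3.0)
      cp$cl_per_kg <- draw_valid(compound$cl_per_kg,
                                 function(cl) cl * bw < settings$q_h)
      validate_compound(cp)
    })
  })
  out <- c(list(compound), perturbed)
  names(out) <- paste0("err", seq_along(out) - 1L)
  attr(out, "redraws") <- redraws
  out
}

#' DQI-HLD vertices for a compound
#'
#' Runs the full pipeline for one compound and one steady-state quantity:
#' each input-data scenario (the original alone, or the original plus the
#' Gaussian error scenarios) is simulated under all five
#' distribution-kinetics scenarios, and each simulation's dose sweep is
#' reduced to a (HLD, DQI) coordinate pair.  With errors enabled and the
#' default 50 error scenarios this yields 5 x 51 = 255 vertices.
#'
#' @param compound A [compound()].
#' @param settings A [model_settings()].
#' @param quantity Quantity name (see [steady_state_quantities()]).
#' @param errors Include the Gaussian input-error ensemble?
#' @param seed Seed for the error draws (default: a stable per-compound
#'   offset of the settings seed).
#' @return A data.frame with columns `input_scenario`, `dist_scenario`,
#'   `hld`, `dqi`.
#' @export
dqi_hld_vertices <- function(compound, settings = model_settings(),
                             quantity = "css_central_max", errors = TRUE,
                             seed = .compound_seed(settings$rng_seed,
                                                   compound$name)) {
  inputs <- if (errors) {
    make_error_scenarios(compound, settings, seed = seed)
  } else {
    stats::setNames(list(compound), "err0")
  }
  rows <- list()
  for (inm in names(inputs)) {
    cp <- inputs[[inm]]
    scenarios <- make_scenarios(cp, settings)
    for (sc in scenarios) {
      curves <- run_dose_sweep(cp, sc, settings, quantities = quantity)
      est <- estimate_dqi_hld(curves[[quantity]], settings)
      rows[[length(rows) + 1L]] <- data.frame(
        input_scenario = inm, dist_scenario = sc$scenario_id,
        hld = est$hld, dqi = est$dqi)
    }
  }
  do.call(rbind, rows)
}

#' Polygon metrics of a DQI-HLD vertex cloud
#'
#' Orders the vertices into a non-self-intersecting closed polygon and
#' computes its area (shoelace formula), area centroid, and second moments
#' of area.  `second_moment_hld` is the moment of area about the HLD (x)
#' axis, `integral(dqi^2 dA)`, and `second_moment_dqi` the moment about
#' the DQI (y) axis, `integral(hld^2 dA)` -- the engineering convention,
#' in which each moment is named for the axis it is taken about; the
#' translation-invariant centroidal counterparts (about axes through the
#' centroid) are returned alongside.  The default ordering takes the
#' convex hull of the cloud, which weights the outer envelope of the
#' scenario/error ensemble; `ordering = "angular"` instead sorts all
#' vertices by angle about their arithmetic mean, producing a star-shaped
#' polygon that threads every vertex.  Collinear or coincident vertex sets
#' degenerate to area 0 with the centroid at the vertex mean.
#'
#' @param vertices A data.frame or matrix with columns `hld` and `dqi`;
#'   at least 3 vertices.
#' @param ordering `"hull"` (default) or `"angular"`.
#' @return An object of class `dqi_hld_polygon`: `vertices` (the input
#'   cloud), `boundary` (the ordered polygon vertices), `area`, `centroid`
#'   (named c(hld, dqi)), `second_moment_hld`, `second_moment_dqi`,
#'   `second_moment_hld_centroidal`, `second_moment_dqi_centroidal`,
#'   `vertex_mean`, `n_vertices` (size of the input cloud), `ordering`.
#' @export
#' @examples
#' sq <- data.frame(hld = c(0, 1, 1, 0), dqi = c(0, 0, 1, 1))
#' p <- build_polygon(sq)
#' p$area                           # 1
#' p$second_moment_hld_centroidal   # 1/12
build_polygon <- function(vertices, ordering = c("hull", "angular")) {
  ordering <- match.arg(ordering)
  cloud <- as.matrix(as.data.frame(vertices)[, c("hld", "dqi")])
  if (nrow(cloud) < 3)
    stop("a polygon needs at least 3 vertices", call. = FALSE)
  mean_pt <- colMeans(cloud)
  v <- cloud

  if (ordering == "angular") {
    ang <- atan2(v[, "dqi"] - mean_pt["dqi"], v[, "hld"] - mean_pt["hld"])
    v <- v[order(ang), , drop = FALSE]
  } else {
    v <- v[rev(grDevices::chull(v[, "hld"], v[, "dqi"])), , drop = FALSE]
  }

  # shoelace sums on mean-shifted coordinates for numerical stability;
  # origin moments are recovered by the parallel-axis theorem afterwards
  x <- v[, "hld"] - mean_pt["hld"]
  y <- v[, "dqi"] - mean_pt["dqi"]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a_signed <- sum(cross) / 2
  scale2 <- max(x^2 + y^2, 1e-300)
  degenerate <- abs(a_signed) < 1e-14 * scale2
  if (degenerate) {
    cen <- c(hld = unname(mean_pt["hld"]), dqi = unname(mean_pt["dqi"]))
    out <- list(vertices = cloud, boundary = v, area = 0, centroid = cen,
                second_moment_hld = 0, second_moment_dqi = 0,
                second_moment_hld_centroidal = 0,
                second_moment_dqi_centroidal = 0,
                vertex_mean = mean_pt, n_vertices = nrow(cloud),
                ordering = ordering)
    class(out) <- "dqi_hld_polygon"
    return(out)
  }
  s <- sign(a_signed)
  area <- abs(a_signed)
  cx <- sum((x + xn) * cross) / (6 * a_signed)
  cy <- sum((y + yn) * cross) / (6 * a_signed)
  ixx <- s * sum((y^2 + y * yn + yn^2) * cross) / 12  # integral y^2 dA
  iyy <- s * sum((x^2 + x * xn + xn^2) * cross) / 12  # integral x^2 dA
  # centroidal moments, then shift to the true coordinate axes
  ixx_c <- ixx - area * cy^2
  iyy_c <- iyy - area * cx^2
  cen_hld <- unname(cx + mean_pt["hld"])
  cen_dqi <- unname(cy + mean_pt["dqi"])
  out <- list(
    vertices = cloud,
    boundary = v,
    area = area,
    centroid = c(hld = cen_hld, dqi = cen_dqi),
    second_moment_hld = ixx_c + area * cen_dqi^2,
    second_moment_dqi = iyy_c + area * cen_hld^2,
    second_moment_hld_centroidal = ixx_c,
    second_moment_dqi_centroidal = iyy_c,
    vertex_mean = mean_pt,
    n_vertices = nrow(cloud),
    ordering = ordering
  )
  class(out) <- "dqi_hld_polygon"
  out
}

#' @export
print.dqi_hld_polygon <- function(x, ...) {
  cat(sprintf(
    "<dqi_hld_polygon> %d vertices (%s order): area %.4g, centroid (HLD %.3f, DQI %.3f)\n",
    x$n_vertices, x$ordering, x$area, x$centroid["hld"], x$centroid["dqi"]))
  cat(sprintf("  second moments of area: HLD %.4g, DQI %.4g\n",
              x$second_moment_hld, x$second_moment_dqi))
  invisible(x)
}

#' Per-compound DQI-HLD polygon summary table
#'
#' Runs the full pipeline for each compound and tabulates its DQI-HLD
#' polygon metrics: area, second moments of area in the HLD and DQI
#' dimensions, and the centroid coordinates (plus the plain vertex mean
#' for reference).  With `errors = TRUE` each polygon has 255 vertices
#' (5 distribution scenarios x 51 input scenarios); with `errors = FALSE`
#' it has the 5 distribution-scenario vertices only.
#'
#' @param compounds A `compound_set` or list of [compound()]s.
#' @param settings A [model_settings()].
#' @param quantity Quantity name.
#' @param errors Include the Gaussian input-error ensemble?
#' @param seed Base seed (per-compound offsets are derived from it).
#' @param ordering Polygon vertex ordering, see [build_polygon()].
#' @return A data.frame with one row per compound.
#' @export
suitability_summary <- function(compounds, settings = model_settings(),
                                quantity = "css_central_max", errors = TRUE,
                                seed = settings$rng_seed,
                                ordering = "hull") {
  rows <- lapply(compounds, function(cp) {
    verts <- dqi_hld_vertices(cp, settings, quantity = quantity,
                              errors = errors,
                              seed = .compound_seed(seed, cp$name))
    poly <- build_polygon(verts, ordering = ordering)
    data.frame(compound = cp$name,
               quantity = quantity,
               n_vertices = poly$n_vertices,
               area = poly$area,
               second_moment_hld = poly$second_moment_hld,
               second_moment_dqi = poly$second_moment_dqi,
               centroid_hld = unname(poly$centroid["hld"]),
               centroid_dqi = unname(poly$centroid["dqi"]),
               vertex_mean_hld = unname(poly$vertex_mean["hld"]),
               vertex_mean_dqi = unname(poly$vertex_mean["dqi"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot DQI-HLD polygons
#'
#' Draws each compound's polygon (and its centroid) in the DQI (y) versus
#' HLD (x) plane.
#'
#' @param polygons A named list of `dqi_hld_polygon` objects.
#' @param col Outline colours, recycled.
#' @param ... Passed to [graphics::plot()].
#' @return The polygon list, invisibly.
#' @export
plot_dqi_hld <- function(polygons, col = seq_along(polygons) + 1, ...) {
  all_v <- do.call(rbind, lapply(polygons, `[[`, "vertices"))
  graphics::plot(all_v[, "hld"], all_v[, "dqi"], type = "n",
                 xlab = "HLD (log10 mg)", ylab = "DQI", ...)
  col <- rep_len(col, length(polygons))
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    graphics::polygon(p$boundary[, "hld"], p$boundary[, "dqi"],
                      border = col[i])
    graphics::points(p$centroid["hld"], p$centroid["dqi"], pch = 19,
                     col = col[i])
    if (!is.null(names(polygons)))
      graphics::text(p$centroid["hld"], p$centroid["dqi"],
                     labels = names(polygons)[i], pos = 3, cex = 0.7,
                     col = col[i])
  }
  invisible(polygons)
}
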