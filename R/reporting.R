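#' Data behind a compositional geometric-mean bar plot
#'
#' For every factor level and part, the bar height is the log-ratio of the
#' level's closed compositional-mean share to the whole sample's:
#' `ln(mean_level[part] / mean_all[part])`, both means closed. The zero
#' line is the overall mean; bars above it mark parts over-represented in
#' that level.
#'
#' @param cohort a [build_cohort()] result (imputed).
#' @param factor sociodemographic column name.
#' @param family `"intensity"` or `"type"`.
#' @return Data frame: `level`, `part`, `logratio`.
#' @export
gmean_barplot_data <- function(cohort, factor,
                               family = c("intensity", "type")) {
  family <- match.arg(family)
  m <- composition_matrix(cohort, family)
  g <- as.data.frame(cohort)[match(rownames(m), cohort$child_id), factor]
  keep <- !is.na(g)
  m <- m[keep, , drop = FALSE]
  g <- g[keep]
  all_mean <- compositional_mean(m, 1)
  rows <- lapply(sort(unique(g)), function(lev) {
    lm <- compositional_mean(m[g == lev, , drop = FALSE], 1)
    data.frame(level = lev, part = colnames(m),
               logratio = as.numeric(log(lm / all_mean)))
  })
  out <- do.call(rbind, rows)
  out$part <- base::factor(out$part, levels = colnames(m))
  rownames(out) <- NULL
  out
}

#' Ternary-plot coordinates for a 3-part subcomposition
#'
#' Re-closes each row over three chosen parts, maps barycentric shares to
#' Cartesian coordinates of an equilateral triangle (vertices at (0,0),
#' (1,0) and (1/2, sqrt(3)/2)), and, per group, returns the closed
#' geometric-mean centre and a confidence ellipse. The ellipse is the
#' chi-square quantile ellipse (df = 2) of a bivariate normal fitted to
#' the 2-D ilr coordinates of the subcomposition, mapped back through the
#' inverse ilr as a polygon.
#'
#' @param x composition matrix (any closure constant).
#' @param parts three part names.
#' @param group optional grouping vector (one entry per row).
#' @param conf ellipse coverage (default 0.95).
#' @param n_vertices polygon resolution.
#' @return List: `points` (x, y, group), `centres` (group, x, y),
#'   `ellipses` (group, x, y polygon vertices).
#' @export
ternary_coordinates <- function(x, parts, group = NULL, conf = 0.95,
                                n_vertices = 100) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (length(parts) != 3)
    stop("a ternary plot needs exactly 3 parts", call. = FALSE)
  if (!all(parts %in% colnames(x)))
    stop("part(s) not found: ",
         paste(setdiff(parts, colnames(x)), collapse = ", "), call. = FALSE)
  sub <- closure(x[, parts, drop = FALSE], 1)
  .check_positive(sub, "subcomposition")
  bary2cart <- function(s) {
    s <- if (is.matrix(s)) s else matrix(s, nrow = 1)
    cbind(x = s[, 2] + 0.5 * s[, 3], y = sqrt(3) / 2 * s[, 3])
  }
  g <- if (is.null(group)) rep("all", nrow(sub)) else as.character(group)
  pts <- data.frame(bary2cart(sub), group = g)
  basis <- pivot_basis(3, parts)
  centres <- list()
  ellipses <- list()
  for (lev in unique(g)) {
    si <- sub[g == lev, , drop = FALSE]
    cen <- compositional_mean(si, 1)
    centres[[lev]] <- data.frame(group = lev, bary2cart(cen))
    if (nrow(si) >= 3) {
      z <- ilr_transform(si, basis)
      mu <- colMeans(z)
      S <- stats::cov(z)
      r <- sqrt(stats::qchisq(conf, df = 2))
      th <- seq(0, 2 * pi, length.out = n_vertices)
      circ <- cbind(cos(th), sin(th))
      ez <- sweep(r * circ %*% chol(S), 2, mu, `+`)
      epoly <- ilr_inverse(ez, basis, 1)
      ellipses[[lev]] <- data.frame(group = lev, bary2cart(epoly))
    }
  }
  list(points = pts,
       centres = do.call(rbind, c(centres, list(make.row.names = FALSE))),
       ellipses = if (length(ellipses))
         do.call(rbind, c(ellipses, list(make.row.names = FALSE))) else NULL)
}

#' Render a compositional geometric-mean bar plot
#'
#' @param bar_data a [gmean_barplot_data()] result.
#' @return A ggplot object.
#' @export
plot_gmean_bars <- function(bar_data) {
  ggplot2::ggplot(bar_data,
                  ggplot2::aes(x = .data$part, y = .data$logratio,
                               fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "log-ratio vs. overall compositional mean",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Render a ternary plot with group centres and confidence ellipses
#'
#' @param tern a [ternary_coordinates()] result.
#' @param parts the three part names (used for vertex labels).
#' @return A ggplot object.
#' @export
plot_ternary <- function(tern, parts = NULL) {
  tri <- data.frame(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = tri, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = tern$points,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = tern$centres,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group),
                        shape = 17, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(tern$ellipses))
    p <- p + ggplot2::geom_path(data = tern$ellipses,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$group))
  if (!is.null(parts))
    p <- p + ggplot2::annotate("text",
                               x = c(-0.03, 1.03, 0.5),
                               y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                               label = parts)
  p
}
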