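# Shared fixtures, built in code.

unit_ball <- ball_area_function(1)

# toy estimation-ready series used across the worked examples:
# areas (0,2,3,0) over unit gaps, and over gaps (1,1,2)
toy_const <- section_series(c(0, 1, 2, 3), c(0, 2, 3, 0))
toy_uneq <- section_series(c(0, 1, 2, 4), c(0, 2, 3, 0))

# random estimation-ready series (zero end areas, positive interior)
random_series <- function(n_interior = 6, equidistant = FALSE) {
  gaps <- if (equidistant) rep(runif(1, 0.5, 2), n_interior + 1)
          else runif(n_interior + 1, 0.5, 2)
  pos <- cumsum(c(0, gaps))
  areas <- c(0, runif(n_interior, 0.1, 5), 0)
  section_series(pos, areas)
}

# independent fine-grid trapezoid quadrature (oracle for volumes)
trapz_quad <- function(f, lo, hi, n = 2e5) {
  x <- seq(lo, hi, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
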