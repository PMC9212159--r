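#' Generate synthetic example datasets
#'
#' Builds small synthetic datasets shaped like the data the method targets,
#' so examples and tests run self-contained. Three kinds:
#' \describe{
#'   \item{`th17_like`}{8 variables x 5 time points (0, 12, 24, 48, 72 h) x
#'     3 replicates in each of two conditions ("Th0", "Th17"; 6 replicate
#'     slots, condition-tagged). Contains an induced marker, two genes
#'     co-expressed with it, one complementary (anti-phase) gene, two
#'     condition-invariant genes (targets for [self_cor_screen()]), and
#'     two background genes, with multiplicative noise.}
#'   \item{`yeast_alpha_like`}{4 variables x 18 time points (0-119 min, 7
#'     min apart) covering two 60-minute cycles, one replicate: two
#'     similar-phased cyclic genes and two anti-phased ones, with additive
#'     noise. Split cycles into replicates with
#'     [split_series_replicates()].}
#'   \item{`worked_example`}{a 2-variable, 3-time-point pair placed so that
#'     the RBF Gram matrix at `gamma = 0.5` (without standardization) is
#'     `[[1,0,0],[0,1,0.988],[0,0.988,1]]` to 3 decimals: the two near
#'     points sit `sqrt(-log(0.988)/0.5)` apart in the plane and the third
#'     far away. Deterministic.}
#' }
#' All output is synthetic; it emulates dataset shapes, not any real
#' measurements.
#'
#' @param kind One of `"th17_like"`, `"yeast_alpha_like"`,
#'   `"worked_example"`.
#' @param seed Integer seed for the noise draws.
#' @return An [expression_dataset()]. For `"worked_example"` the RBF width
#'   that reproduces the Gram matrix is attached as attribute `"gamma"`.
#' @export
make_fixtures <- function(kind = c("th17_like", "yeast_alpha_like",
                                   "worked_example"), seed = 1) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  switch(kind,
         th17_like = fixture_th17(),
         yeast_alpha_like = fixture_yeast(),
         worked_example = fixture_worked_example())
}

fixture_th17 <- function() {
  times <- c(0, 12, 24, 48, 72)
  tt <- times / 72
  profiles <- list(
    marker    = list(th0 = rep(20, 5),            th17 = 20 + 480 * tt^2),
    coexpr1   = list(th0 = rep(50, 5),            th17 = 50 + 400 * tt^2),
    coexpr2   = list(th0 = 80 - 20 * tt,          th17 = 80 + 350 * tt^1.5),
    anti1     = list(th0 = rep(300, 5),           th17 = 320 - 280 * tt^0.8),
    invariant1 = list(th0 = 200 + 150 * sin(pi * tt),
                      th17 = 200 + 150 * sin(pi * tt)),
    invariant2 = list(th0 = 400 - 250 * tt,       th17 = 400 - 250 * tt),
    background1 = list(th0 = 120 + 30 * tt,       th17 = 100 + 10 * tt),
    background2 = list(th0 = 60 + 40 * sin(2 * pi * tt),
                       th17 = 70 - 25 * tt)
  )
  vars <- names(profiles)
  condition <- rep(c("Th0", "Th17"), each = 3L)
  values <- array(NA_real_, dim = c(length(vars), length(times), 6L))
  for (i in seq_along(vars)) {
    for (r in 1:6) {
      base <- if (condition[r] == "Th0") profiles[[i]]$th0
              else profiles[[i]]$th17
      values[i, , r] <- base * exp(stats::rnorm(length(times), sd = 0.05))
    }
  }
  expression_dataset(values, vars, times, condition)
}

fixture_yeast <- function() {
  times <- seq(0, 119, by = 7)
  phase <- 2 * pi * times / 60  # two cycles across the series
  profiles <- rbind(
    cyc_a = 2.0 * sin(phase),
    cyc_b = 1.8 * sin(phase - pi / 6),
    cyc_c = -2.0 * sin(phase) + 0.5,
    cyc_d = 1.6 * sin(phase + pi - pi / 8) - 0.3
  )
  noise <- matrix(stats::rnorm(length(profiles), sd = 0.15),
                  nrow = nrow(profiles))
  expression_dataset(profiles + noise, rownames(profiles), times)
}

fixture_worked_example <- function() {
  gamma <- 0.5
  d23 <- sqrt(-log(0.988) / gamma)
  x <- c(10, 0, d23)
  y <- c(10, 0, 0)
  ds <- expression_dataset(rbind(v1 = x, v2 = y), c("v1", "v2"), 1:3)
  attr(ds, "gamma") <- gamma
  ds
}
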