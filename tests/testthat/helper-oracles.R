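# Independent oracles used to cross-check the package implementations.
# Each is written from the defining formula, not by calling package code.

# Windowed quadrature Gabor energy by direct summation at one point.
# psi is the carrier direction; wavelength 2*sigma; isotropic envelope.
oracle_gabor_energy <- function(img, row, col, sigma, psi) {
  radius <- ceiling(3 * sigma)
  even_sum <- 0
  odd_sum <- 0
  env_tot <- 0
  ev_tot <- 0
  # accumulate kernel first to mean-correct the even part
  dr <- -radius:radius
  ev <- od <- en <- matrix(0, length(dr), length(dr))
  for (i in seq_along(dr)) for (j in seq_along(dr)) {
    y <- dr[i]; x <- dr[j]
    g <- exp(-(x^2 + y^2) / (2 * sigma^2))
    ph <- 2 * pi * (x * cos(psi) + y * sin(psi)) / (2 * sigma)
    en[i, j] <- g
    ev[i, j] <- g * cos(ph)
    od[i, j] <- g * sin(ph)
  }
  ev <- ev - en * sum(ev) / sum(en)
  nr <- nrow(img); nc <- ncol(img)
  for (i in seq_along(dr)) for (j in seq_along(dr)) {
    r <- row + dr[i]; c <- col + dr[j]
    # symmetric padding, matching the implementation contract that the
    # filter support may leave the image
    r <- if (r < 1) 1 - r else if (r > nr) 2 * nr - r else r
    c <- if (c < 1) 1 - c else if (c > nc) 2 * nc - c else c
    r <- min(max(r, 1), nr); c <- min(max(c, 1), nc)
    even_sum <- even_sum + img[r, c] * ev[i, j]
    odd_sum <- odd_sum + img[r, c] * od[i, j]
  }
  sqrt(even_sum^2 + odd_sum^2)
}

# Type III sum of squares for one term by model comparison: RSS of the
# model dropping the term's columns (sum-to-zero coding) minus full RSS.
oracle_type3_ss <- function(frame, response) {
  y <- frame[[response]]
  sp <- ifelse(frame$species == sort(unique(frame$species))[1], 1, -1)
  sx <- ifelse(frame$sex == sort(unique(frame$sex))[1], 1, -1)
  X <- cbind(1, sp, sx, sp * sx)
  rss <- function(M) {
    fit <- lm.fit(M, y)
    sum(fit$residuals^2)
  }
  full <- rss(X)
  c(species = rss(X[, -2, drop = FALSE]) - full,
    sex = rss(X[, -3, drop = FALSE]) - full,
    `species:sex` = rss(X[, -4, drop = FALSE]) - full,
    Residuals = full)
}

# Classical balanced two-way decomposition from cell means.
oracle_balanced_ss <- function(frame, response) {
  y <- frame[[response]]
  a <- factor(frame$species); b <- factor(frame$sex)
  n_cell <- table(a, b)
  stopifnot(length(unique(c(n_cell))) == 1)
  m <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, list(a, b), mean)
  nc <- c(n_cell)[1]
  ss_a <- nlevels(b) * nc * sum((ma - m)^2)
  ss_b <- nlevels(a) * nc * sum((mb - m)^2)
  ss_ab <- nc * sum((sweep(sweep(mab, 1, ma), 2, mb) + m)^2)
  ss_e <- sum((y - mab[cbind(a, b)])^2)
  c(species = ss_a, sex = ss_b, `species:sex` = ss_ab, Residuals = ss_e)
}

# Small deterministic test stack: three channel matrices with metadata.
toy_stack <- function(nr = 8, nc = 8, values = NULL, ppmm = 17) {
  if (is.null(values)) values <- matrix(seq_len(nr * nc) * 10, nr, nc)
  mspec_stack(values, values, values, pixels_per_mm = ppmm)
}

# A filled disc mask centred in an n x n image.
disc_mask <- function(n, radius, role = "target") {
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`))
  region_mask(d <= radius, role)
}

# Balanced random factor frame for the statistics tests.
make_frame <- function(n_cell = 5, effects = c(species = 0, sex = 0,
                                               inter = 0), sd = 1) {
  g <- expand.grid(species = c("sp1", "sp2"), sex = c("f", "m"),
                   rep = seq_len(n_cell), stringsAsFactors = FALSE)
  mu <- effects[["species"]] * (g$species == "sp2") +
    effects[["sex"]] * (g$sex == "m") +
    effects[["inter"]] * (g$species == "sp2") * (g$sex == "m")
  g$y <- mu + rnorm(nrow(g), 0, sd)
  g
}

# Evaluate expr under a temporary seed without touching the session RNG.
with_seed_acc <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
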