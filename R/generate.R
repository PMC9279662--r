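# -- image simulation -------------------------------------------------------

shift_axis_rep <- function(a, t, axis) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + t, 1L), n)
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# separable Gaussian smoothing with replicate-edge handling
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  for (ax in 1:3) {
    out <- array(0, dim(a))
    for (k in seq(-r, r)) {
      out <- out + w[k + r + 1] * shift_axis_rep(a, k, ax)
    }
    a <- out
  }
  a
}

ellipsoid_mask <- function(shape, spacing, center_mm, semi_axes_mm) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  dx <- (g$x - 0.5) * spacing[1] - center_mm[1]
  dy <- (g$y - 0.5) * spacing[2] - center_mm[2]
  dz <- (g$z - 0.5) * spacing[3] - center_mm[3]
  inside <- (dx / semi_axes_mm[1])^2 + (dy / semi_axes_mm[2])^2 +
    (dz / semi_axes_mm[3])^2 <= 1
  array(inside, shape)
}

# one patient's 8-channel tumor volume with the group-dependent planted
# effects baked into the in-tumor noise field
simulate_study <- function(id, config, non_os) {
  shape <- config$volume_shape
  sp <- config$voxel_spacing_mm
  extent <- shape * sp
  r <- runif(1, config$tumor_radius_range_mm[1], config$tumor_radius_range_mm[2])
  ax <- r * runif(3, 0.85, 1.15)
  ax <- pmin(ax, extent / 2 - sp)  # keep the tumor inside the volume
  center <- extent / 2 + runif(3, -1, 1)
  mask <- ellipsoid_mask(shape, sp, center, ax)

  eff <- config$effect_sizes
  g_i <- as.numeric(non_os)
  sigma <- 0.8 + eff$texture_correlation_length * g_i
  nvox <- sum(mask)

  channels <- list()
  for (ch in config$channels) {
    bg <- array(rnorm(prod(shape)), shape)
    field <- gaussian_smooth3(array(rnorm(prod(shape)), shape), sigma)
    fv <- field[mask]
    fv <- (fv - mean(fv)) / max(sd(fv), 1e-12)
    lw <- rnorm(nvox, 0, 1)
    skew_comp <- (exp(lw) - exp(0.5)) / sqrt((exp(1) - 1) * exp(1))
    vol <- bg
    vol[mask] <- 2 + eff$mean_intensity_shift * g_i + fv +
      eff$histogram_skewness_shift * g_i * skew_comp
    channels[[ch]] <- vol
  }
  mp_study(id, channels, mask, sp)
}

# OS-label draw, split out so prevalence behavior is testable at large n
cohort_labels <- function(config) {
  set.seed(child_seed(config$seed, "labels"))
  rbinom(config$n_patients, 1L, 1 - config$os_fraction) == 1L
}

# -- clinical table simulation ----------------------------------------------

rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

sample_level <- function(n, counts_tbl, group) {
  p <- counts_tbl[[group]]
  sample(counts_tbl$level, n, replace = TRUE, prob = p / sum(p))
}

# one clinical record drawn from the OS-group-conditional reference
# marginals; stage/cN and the nodal counts are generated jointly so the
# clinical invariants hold
simulate_clinical <- function(id, non_os) {
  grp <- if (non_os) "nonos" else "os"
  s1 <- function(v) sample_level(1L, pooled_group_counts(v), grp)
  stage <- s1("stage")
  if (startsWith(stage, "II") && !startsWith(stage, "III")) {
    c_n <- "N0"
  } else {
    cn_tbl <- dplyr::filter(pooled_group_counts("c_n"), .data$level != "N0")
    c_n <- sample_level(1L, cn_tbl, grp)
  }
  y_n <- s1("y_n")
  positive_ln <- switch(y_n, N0 = 0L, N1 = sample(1:3, 1L),
                        N2 = sample(4:9, 1L))
  total_ln <- max(positive_ln + 1L,
                  as.integer(round(rtnorm(1, if (non_os) 13 else 16,
                                          6.5, 3, 37))))
  surgery_p <- if (non_os) c(LAR = 0.47, APR = 0.21, Hartmann = 0.26,
                             other = 0.06)
               else c(LAR = 0.66, APR = 0.18, Hartmann = 0.10, other = 0.06)
  surv <- if (non_os) rtnorm(1, 32, 15, 5, 59.9) else rtnorm(1, 82, 15, 60, 121)
  tibble(
    patient_id = id,
    age = round(rtnorm(1, if (non_os) 67 else 62, 12, 19, 89)),
    gender = s1("gender"),
    cea = round(exp(rnorm(1, if (non_os) 2.2 else 1.2,
                          if (non_os) 1.3 else 1.1)), 1),
    c_t = s1("c_t"),
    c_n = c_n,
    stage = stage,
    tumor_deposit = runif(1) < (if (non_os) 23 / 37 else 30 / 75),
    surgery = sample(names(surgery_p), 1L, prob = surgery_p),
    chemo = s1("chemo"),
    location = s1("location"),
    dist_anal_verge = round(rtnorm(1, if (non_os) 9.5 else 8.1,
                                   if (non_os) 4.2 else 3.2, 1, 20), 1),
    emvi = as.integer(s1("emvi")),
    y_t = s1("y_t"),
    y_n = y_n,
    total_ln = total_ln,
    positive_ln = positive_ln,
    lnr = positive_ln / total_ln,
    histology = s1("histology"),
    survival_months = round(surv, 1),
    os_5yr = !non_os
  )
}

#' Generate a synthetic multiparametric cohort
#'
#' Draws `n_patients` patients: a 5-year OS label at the configured
#' prevalence, an ellipsoidal tumor filled with correlated Gaussian noise
#' whose correlation length, skewness, and mean differ between OS groups by
#' the configured effect sizes (identically in all channels, with
#' independent noise per channel), and a clinical record sampled from the
#' OS-group-conditional reference cohort marginals. Bit-identical for a
#' fixed seed.
#'
#' @param config a [cohort_config()].
#' @return list with `studies` (list of `mp_study`), `clinical` (tibble,
#'   one row per patient), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  non_os <- cohort_labels(config)
  ids <- sprintf("pt%03d", seq_len(n))
  studies <- vector("list", n)
  clinical <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(child_seed(config$seed, paste0("img", i)))
    studies[[i]] <- simulate_study(ids[i], config, non_os[i])
    set.seed(child_seed(config$seed, paste0("clin", i)))
    clinical[[i]] <- simulate_clinical(ids[i], non_os[i])
  }
  list(studies = studies, clinical = dplyr::bind_rows(clinical),
       config = config)
}
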