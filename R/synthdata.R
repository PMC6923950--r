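## Synthetic datasets with the statistical structure the inference
## assumes: replicated optical-density growth curves on a 15-min grid,
## steady-state composition observations at 80 h, and colony
## footprint-area series sampled every 20 min.

#' Growth-curve dataset
#'
#' Container for the averaged growth curve and the composition
#' observations entering the likelihood: per-timepoint mean total mass
#' `D_k` and sample variance `v_k`, plus the observed ethanol-state and
#' quiescent-state mass fractions at `t_N` with their uncertainties.
#'
#' @param times timepoints `t_k` (hours).
#' @param mean_mass averaged total cell mass `D_k`.
#' @param var_mass per-timepoint sample variances `v_k` (floored at
#'   `1e-8`).
#' @param n_replicates number of replicates averaged.
#' @param alpha_e,alpha_q observed composition fractions at `t_N`.
#' @param sigma_alpha_e,sigma_alpha_q their standard deviations.
#' @param t_N composition observation time (hours).
#' @param replicates optional matrix of per-replicate curves
#'   (`length(times) x n_replicates`).
#' @return list of class `growth_dataset`.
#' @export
growth_dataset <- function(times, mean_mass, var_mass, n_replicates,
                           alpha_e, alpha_q, sigma_alpha_e = 0.02,
                           sigma_alpha_q = 0.02, t_N = 80,
                           replicates = NULL) {
  stopifnot(length(times) == length(mean_mass),
            length(times) == length(var_mass))
  if (length(times) && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  var_mass <- pmax(var_mass, 1e-8)
  if (alpha_e < 0 || alpha_q < 0 || alpha_e + alpha_q > 1)
    stop("composition fractions must be in [0,1] and sum to at most 1")
  if (sigma_alpha_e <= 0 || sigma_alpha_q <= 0)
    stop("composition standard deviations must be positive")
  if (length(times) && t_N > max(times))
    stop("t_N must not exceed the last timepoint")
  structure(list(times = as.numeric(times),
                 mean_mass = as.numeric(mean_mass),
                 var_mass = as.numeric(var_mass),
                 n_replicates = as.integer(n_replicates),
                 alpha_e = alpha_e, alpha_q = alpha_q,
                 sigma_alpha_e = sigma_alpha_e,
                 sigma_alpha_q = sigma_alpha_q, t_N = t_N,
                 replicates = replicates),
            class = "growth_dataset")
}

#' Footprint-area dataset
#'
#' @param times imaging timepoints (hours).
#' @param area_mm2 measured footprint areas (mm^2).
#' @param replicate replicate identifier.
#' @return list of class `footprint_dataset`.
#' @export
footprint_dataset <- function(times, area_mm2, replicate = 1L) {
  stopifnot(length(times) == length(area_mm2))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(area_mm2 < 0)) stop("areas must be non-negative")
  structure(list(times = as.numeric(times), area_mm2 = as.numeric(area_mm2),
                 replicate = as.integer(replicate)),
            class = "footprint_dataset")
}

#' Generate replicated synthetic growth curves with composition data
#'
#' Emulates the calibration design: total cell mass sampled every 15 min
#' for 88 h in `n_replicates` wells with additive i.i.d. normal
#' measurement noise, averaged into `D_k` with sample variances `v_k`,
#' plus composition observations at `t_N` drawn from the true trajectory
#' fractions with normal noise truncated (by rejection) to keep the
#' fractions valid.
#'
#' @param truth log-scale ground-truth parameter vector (default
#'   [default_truth_theta()]).
#' @param hyp hypothesis under which `truth` is interpreted.
#' @param n_replicates number of replicate growth curves (>= 2).
#' @param noise_sd replicate measurement noise standard deviation
#'   (OD-equivalent mass units).
#' @param t_max,dt grid extent and spacing (hours).
#' @param t_N composition observation time.
#' @param sigma_alpha standard deviation of the composition observations.
#' @param seed optional RNG seed.
#' @return a [growth_dataset()].
#' @export
generate_growth_curves <- function(truth = default_truth_theta(),
                                   hyp = "H2", n_replicates = 6,
                                   noise_sd = 0.01, t_max = 88, dt = 0.25,
                                   t_N = 80, sigma_alpha = 0.02,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_replicates < 2) stop("need at least two replicates")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  pv <- params_from_vector(truth, hyp)
  times <- seq(0, t_max, by = dt)
  traj <- simulate_microenv(pv$params, pv$init, times, hyp)
  m <- total_mass(traj)
  if (any(!is.finite(m))) stop("ground truth produced a non-finite trajectory")
  reps <- matrix(rnorm(length(m) * n_replicates, mean = m, sd = noise_sd),
                 length(m), n_replicates)
  fr <- steady_fractions(traj, t_N)
  rtrunc01 <- function(mean, sd) {
    if (sd == 0) return(mean)
    repeat {
      x <- rnorm(1, mean, sd)
      if (x >= 0 && x <= 1) return(x)
    }
  }
  a_e <- rtrunc01(fr[["frac_e"]], sigma_alpha)
  a_q <- rtrunc01(fr[["frac_q"]], sigma_alpha)
  growth_dataset(times = times, mean_mass = rowMeans(reps),
                 var_mass = apply(reps, 1, var),
                 n_replicates = n_replicates, alpha_e = a_e, alpha_q = a_q,
                 sigma_alpha_e = sigma_alpha, sigma_alpha_q = sigma_alpha,
                 t_N = t_N, replicates = reps)
}

#' Generate a synthetic colony footprint-area series
#'
#' Runs the lattice colony simulator at the given nutrient transfer rates
#' and adds zero-truncated normal measurement noise to the sampled
#' footprint areas (every 20 min by default, emulating time-lapse
#' imaging).
#'
#' @param lambda_agar,lambda_col nutrient transfer rates (1/h).
#' @param lattice_config a [lattice_config()].
#' @param params microenvironment parameters for the growing colony.
#' @param hyp hypothesis label.
#' @param horizon simulation horizon (hours, at most 180).
#' @param sampling_dt sampling interval (hours; 1/3 h = 20 min).
#' @param noise_sd measurement noise standard deviation (mm^2).
#' @param seed optional RNG seed.
#' @param replicate replicate identifier.
#' @return a [footprint_dataset()].
#' @export
generate_footprint <- function(lambda_agar, lambda_col,
                               lattice_config = NULL, params = NULL,
                               hyp = "H2", horizon = 48,
                               sampling_dt = 1 / 3, noise_sd = 0,
                               seed = NULL, replicate = 1L) {
  if (!is.null(seed)) set.seed(seed)
  if (horizon > 180) stop("horizon must not exceed 180 h")
  if (is.null(lattice_config)) lattice_config <- lattice_config()
  lattice_config$lambda_agar <- lambda_agar
  lattice_config$lambda_col <- lambda_col
  if (is.null(params))
    params <- params_from_vector(default_truth_theta(), hyp)$params
  sim <- simulate_colony(lattice_config, params, hyp, horizon = horizon,
                         sample_dt = sampling_dt)
  areas <- sim$areas
  if (noise_sd > 0) {
    areas <- vapply(areas, function(a) {
      repeat {
        x <- rnorm(1, a, noise_sd)
        if (x >= 0) return(x)
      }
    }, numeric(1))
  }
  keep <- sim$times > 0
  footprint_dataset(sim$times[keep], areas[keep], replicate = replicate)
}

## ---- delimited-text readers and writers ----
## Numbers are written with 17 significant digits so datasets round-trip
## through the text format bit-exactly.

.fmt <- function(x) sprintf("%.17g", x)

#' Write / read a growth dataset as delimited text
#'
#' The curve is stored as CSV columns `time_h, mean_mass, var_mass`
#' (plus `rep_1..rep_R` when per-replicate curves are present); the
#' composition scalars are stored in `#`-prefixed header lines.
#'
#' @param data a [growth_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(data, path) {
  hdr <- c(sprintf("# n_replicates=%d", data$n_replicates),
           sprintf("# alpha_e=%s", .fmt(data$alpha_e)),
           sprintf("# alpha_q=%s", .fmt(data$alpha_q)),
           sprintf("# sigma_alpha_e=%s", .fmt(data$sigma_alpha_e)),
           sprintf("# sigma_alpha_q=%s", .fmt(data$sigma_alpha_q)),
           sprintf("# t_N=%s", .fmt(data$t_N)))
  df <- data.frame(time_h = .fmt(data$times), mean_mass = .fmt(data$mean_mass),
                   var_mass = .fmt(data$var_mass))
  if (!is.null(data$replicates)) {
    reps <- apply(data$replicates, 2, .fmt)
    colnames(reps) <- sprintf("rep_%d", seq_len(ncol(reps)))
    df <- cbind(df, reps)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_csv
#' @param path file written by [write_growth_csv()].
#' @export
read_growth_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  df <- read.csv(textConnection(lines[!grepl("^#", lines)]))
  repcols <- grep("^rep_", names(df))
  growth_dataset(times = df$time_h, mean_mass = df$mean_mass,
                 var_mass = df$var_mass,
                 n_replicates = as.integer(meta$n_replicates),
                 alpha_e = meta$alpha_e, alpha_q = meta$alpha_q,
                 sigma_alpha_e = meta$sigma_alpha_e,
                 sigma_alpha_q = meta$sigma_alpha_q, t_N = meta$t_N,
                 replicates = if (length(repcols))
                   as.matrix(df[, repcols, drop = FALSE]) else NULL)
}

#' Write / read a footprint dataset as CSV
#'
#' Columns `time_h, area_mm2, replicate`.
#'
#' @param data a [footprint_dataset()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_footprint_csv <- function(data, path) {
  df <- data.frame(time_h = .fmt(data$times), area_mm2 = .fmt(data$area_mm2),
                   replicate = data$replicate)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_footprint_csv
#' @export
read_footprint_csv <- function(path) {
  df <- read.csv(path)
  footprint_dataset(df$time_h, df$area_mm2, replicate = df$replicate[1])
}
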