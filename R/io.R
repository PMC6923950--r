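## Delimited-text and JSON interchange for trajectories and parameters.

#' Export a microenvironment trajectory as CSV
#'
#' Columns `time_h, m_g, m_e, m_q, g, e, m_total`.
#'
#' @param traj a `microenv_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  s <- traj$states
  df <- data.frame(time_h = traj$times, m_g = s[, "m_g"], m_e = s[, "m_e"],
                   m_q = s[, "m_q"], g = s[, "g"], e = s[, "e"],
                   m_total = total_mass(traj))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read microenvironment parameters as JSON
#'
#' Flat key/value JSON using the model's parameter names
#' (`mu1, mu2, beta1, K, beta2, beta3, gamma1, gamma2, gamma3`), plus
#' optionally the initial glucose-state mass `m0`.
#'
#' @param params a [microenv_params()].
#' @param path file path.
#' @param m0 optional initial glucose-state mass to store alongside.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path, m0 = NULL) {
  x <- as.list(unclass(params))
  if (!is.null(m0)) x$m0 <- m0
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @return for the reader: list with `params` and `m0` (`NULL` when
#'   absent).
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- do.call(microenv_params,
               x[intersect(names(x), c("mu1", "mu2", "beta1", "K", "beta2",
                                       "beta3", "gamma1", "gamma2",
                                       "gamma3"))])
  list(params = p, m0 = x$m0)
}

#' Write a chain set to disk
#'
#' One CSV per temperature (samples plus the log-likelihood trace) and a
#' JSON index with the ladder and acceptance statistics, under a common
#' directory.
#'
#' @param chains a `chain_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_chains <- function(chains, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nb <- dim(chains$samples)[3]
  for (i in seq_len(nb)) {
    df <- as.data.frame(chains$samples[, , i])
    names(df) <- paste0("par", seq_len(ncol(df)))
    df$log_lik <- chains$loglik[, i]
    write.csv(df, file.path(dir, sprintf("temperature_%02d.csv", i)),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(ladder = as.numeric(chains$ladder), accept = chains$accept,
         swap_accept = chains$swap_accept,
         hypothesis = chains$hypothesis, seed = chains$seed),
    file.path(dir, "index.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
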