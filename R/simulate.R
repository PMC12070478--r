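#' Configuration for synthetic trap-capture experiments
#'
#' Bundles the generative parameters for both experimental designs. The
#' `"paper2025"` defaults describe the study conditions the simulator
#' emulates: choice trials in which roughly 50 adult thrips are released at
#' the center of a cage with one trap of each pattern size at a common
#' distance (15 trials per distance), with matched-size traps catching about
#' 2.0/1.7/2.1 thrips at 5/10/20 cm and mismatched traps about 0.65; and
#' no-choice polytunnel trials in which counts follow a log-link quadratic in
#' the pattern's maximum resolvable range (peak at 26 cm), with
#' negative-binomial overdispersion, structural zeros, and tunnel and row
#' grouping (3 tunnels x 4 rows).
#'
#' @param n_thrips_per_trial Thrips released per choice trial.
#' @param n_trials Trials per viewing distance (choice design).
#' @param distances_cm Viewing distances tested in the choice design, cm.
#' @param mean_matched Expected catch on the trap whose design distance
#'   matches the trial distance; scalar or one value per distance.
#' @param mean_mismatched Expected catch on mismatched traps.
#' @param dispersion_lab Variance-to-mean ratio of lab counts; 1 is Poisson,
#'   values below 1 give the underdispersion seen in arena counts (via
#'   binomial thinning).
#' @param peak_range_cm Resolvable range at which polytunnel catch peaks, cm.
#' @param curvature Quadratic coefficient (log scale) of the range response;
#'   must be negative for an interior peak.
#' @param baseline_log_mean Intercept of the polytunnel log-mean.
#' @param dispersion Negative-binomial size parameter theta for polytunnel
#'   counts (variance mu + mu^2/theta); large values approach Poisson.
#' @param zero_inflation Probability of a structural zero.
#' @param random_effect_sd_tunnel,random_effect_sd_row Log-scale SDs of the
#'   tunnel and row-within-tunnel effects.
#' @param n_tunnels,n_rows_per_tunnel Polytunnel grouping structure.
#' @param n_replicates Cards per placement within each row.
#' @param seed Default seed used when a simulate call does not pass one.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_thrips_per_trial = 50L,
                       n_trials = 15L,
                       distances_cm = c(5, 10, 20),
                       mean_matched = c(2.0, 1.7, 2.1),
                       mean_mismatched = 0.65,
                       dispersion_lab = 1,
                       peak_range_cm = 26,
                       curvature = -0.0019231,
                       baseline_log_mean = -0.2,
                       dispersion = 2,
                       zero_inflation = 0.15,
                       random_effect_sd_tunnel = 0.25,
                       random_effect_sd_row = 0.25,
                       n_tunnels = 3L,
                       n_rows_per_tunnel = 4L,
                       n_replicates = 1L,
                       seed = 1L) {
  mean_matched <- rep_len(mean_matched, length(distances_cm))
  stopifnot(n_thrips_per_trial >= 0, n_trials >= 1,
            all(mean_matched >= 0), mean_mismatched >= 0,
            dispersion_lab > 0, dispersion > 0,
            zero_inflation >= 0, zero_inflation <= 1,
            random_effect_sd_tunnel >= 0, random_effect_sd_row >= 0)
  structure(
    list(n_thrips_per_trial = as.integer(n_thrips_per_trial),
         n_trials = as.integer(n_trials), distances_cm = distances_cm,
         mean_matched = mean_matched, mean_mismatched = mean_mismatched,
         dispersion_lab = dispersion_lab, peak_range_cm = peak_range_cm,
         curvature = curvature, baseline_log_mean = baseline_log_mean,
         dispersion = dispersion, zero_inflation = zero_inflation,
         random_effect_sd_tunnel = random_effect_sd_tunnel,
         random_effect_sd_row = random_effect_sd_row,
         n_tunnels = as.integer(n_tunnels),
         n_rows_per_tunnel = as.integer(n_rows_per_tunnel),
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' Keys are the arguments of [sim_config()]; missing keys take the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the yaml package is required to read config files", call. = FALSE)
  }
  do.call(sim_config, yaml::read_yaml(path))
}

# run code under a seed, restoring the caller's RNG state afterwards
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# one count with variance-to-mean ratio phi:
# phi == 1 -> Poisson; phi < 1 -> binomial thinning Binomial(N, p) with
# p = 1 - phi, N = mu / p (rounded), giving var/mean = 1 - p = phi.
.rcount_lab <- function(n, mu, phi) {
  if (phi >= 1) return(stats::rpois(n, mu))
  p <- 1 - phi
  N <- pmax(1, round(mu / p))
  stats::rbinom(n, N, pmin(1, mu / N))
}

#' Simulate a choice-arena trap experiment
#'
#' For each trial at each tested distance, one trap of each size class
#' (small, medium, large -- designed to be resolvable at the configured
#' distances) receives a count with expectation `mean_matched` when its
#' design distance equals the trial distance and `mean_mismatched`
#' otherwise. Counts are Poisson (or under-dispersed binomial-thinned when
#' `dispersion_lab < 1`), jointly capped at the number of released thrips by
#' proportional multinomial thinning. With `mode = "multinomial"`, each
#' released thrips is instead assigned to one trap (or escapes) with
#' probabilities proportional to the cell means.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @param mode `"poisson"` (independent counts with cap) or
#'   `"multinomial"` (competition among traps).
#' @return A `capture_dataset` data.frame with columns `design`,
#'   `size_class`, `distance_or_height_cm`, `max_resolvable_range_cm`,
#'   `tunnel_id`, `row_id`, `count`, `trial`.
#' @export
simulate_lab_choice <- function(cfg = sim_config(), seed = cfg$seed,
                                mode = c("poisson", "multinomial")) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  if (3 * max(cfg$mean_matched) > cfg$n_thrips_per_trial &&
      cfg$n_thrips_per_trial > 0) {
    stop("expected catch exceeds the number of released thrips", call. = FALSE)
  }
  k <- length(cfg$distances_cm)
  size_classes <- c("small", "medium", "large")[seq_len(k)]
  .with_seed(seed, {
    rows <- vector("list", k * cfg$n_trials)
    idx <- 1L
    for (di in seq_len(k)) {
      d <- cfg$distances_cm[di]
      for (tr in seq_len(cfg$n_trials)) {
        mu <- ifelse(seq_len(k) == di, cfg$mean_matched[di],
                     cfg$mean_mismatched)
        if (cfg$n_thrips_per_trial == 0) {
          counts <- integer(k)
        } else if (mode == "multinomial") {
          pr <- c(mu, max(0, cfg$n_thrips_per_trial - sum(mu))) /
            cfg$n_thrips_per_trial
          counts <- stats::rmultinom(1, cfg$n_thrips_per_trial, pr)[seq_len(k), 1]
        } else {
          counts <- .rcount_lab(k, mu, cfg$dispersion_lab)
          if (sum(counts) > cfg$n_thrips_per_trial) {
            counts <- stats::rmultinom(1, cfg$n_thrips_per_trial,
                                       counts / sum(counts))[, 1]
          }
        }
        rows[[idx]] <- data.frame(
          design = "lab_choice", size_class = size_classes,
          distance_or_height_cm = d,
          max_resolvable_range_cm = cfg$distances_cm,
          tunnel_id = NA_character_, row_id = NA_character_,
          count = as.integer(counts), trial = tr,
          stringsAsFactors = FALSE)
        idx <- idx + 1L
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("capture_dataset", "data.frame")
    out
  })
}

#' Simulate a polytunnel trap experiment
#'
#' Counts per trap follow a log-link quadratic in the pattern's maximum
#' resolvable range x (0 for placements whose pattern is unresolvable):
#' log mu = b0 + b1 x + b2 x^2 + u_tunnel + u_row, with b2 = `curvature` and
#' b1 = -2 * b2 * `peak_range_cm` so the response peaks at the configured
#' range. Noise is negative-binomial with size `dispersion`; structural
#' zeros occur with probability `zero_inflation`; tunnel and row effects are
#' iid normal on the log scale.
#'
#' @param cfg A [sim_config()].
#' @param placements A [visibility_table()] data.frame (one row per trap
#'   placement within a row of crops); defaults to the nine size-by-height
#'   placements of the polytunnel design.
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return A `capture_dataset` data.frame (see [simulate_lab_choice()]).
#' @export
simulate_polytunnel <- function(cfg = sim_config(),
                                placements = visibility_table(polytunnel_placements()),
                                seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), is.data.frame(placements))
  if (cfg$curvature >= 0) {
    stop("`curvature` must be negative for an interior peak", call. = FALSE)
  }
  b2 <- cfg$curvature
  b1 <- -2 * b2 * cfg$peak_range_cm
  b0 <- cfg$baseline_log_mean
  x <- placements$max_resolvable_range_cm
  .with_seed(seed, {
    rows <- list()
    for (t in seq_len(cfg$n_tunnels)) {
      u_t <- stats::rnorm(1, 0, cfg$random_effect_sd_tunnel)
      for (r in seq_len(cfg$n_rows_per_tunnel)) {
        u_r <- stats::rnorm(1, 0, cfg$random_effect_sd_row)
        for (rep in seq_len(cfg$n_replicates)) {
          mu <- exp(b0 + b1 * x + b2 * x^2 + u_t + u_r)
          counts <- stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion)
          zi <- stats::runif(length(mu)) < cfg$zero_inflation
          counts[zi] <- 0L
          rows[[length(rows) + 1L]] <- data.frame(
            design = "polytunnel",
            size_class = if ("label" %in% names(placements))
              placements$label else NA_character_,
            distance_or_height_cm = placements$height_cm,
            max_resolvable_range_cm = x,
            tunnel_id = sprintf("T%d", t),
            row_id = sprintf("T%d.R%d", t, r),
            count = as.integer(counts), trial = rep,
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("capture_dataset", "data.frame")
    out
  })
}

#' Write / read a capture dataset as tidy CSV
#'
#' Plain CSV with one row per trap per trial; writing the same dataset twice
#' produces byte-identical files, so a simulation rerun with the same config
#' and seed round-trips exactly.
#'
#' @param data A `capture_dataset` data.frame.
#' @param path File path.
#' @return `read_capture_csv()` returns a `capture_dataset`.
#' @export
write_capture_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_capture_csv
#' @export
read_capture_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("capture_dataset", "data.frame")
  out
}
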