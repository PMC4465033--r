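#' Simulate many herds and collect intervention deltas
#'
#' The main experiment: draws `n_herds` herds from the input distributions,
#' simulates each herd's 200-cow population under the baseline and the
#' requested intervention scenarios (sharing the cow population and random
#' draws across branches), and returns one row per herd and intervention
#' with the herd inputs, the intervention-minus-baseline cost delta (gross
#' and net of drug cost, GBP per cow per year) and the methane-intensity
#' delta (g CH4 per L milk).
#'
#' @param n_herds Number of herds (the full experiment uses 10,000).
#' @param n_cows Cows per herd (default 200).
#' @param seed Master seed; herd inputs and every herd's population derive
#'   from it deterministically.
#' @param scenarios Interventions to run.
#' @param herd Optional fixed `herd_params`: when supplied, every herd uses
#'   these inputs (replicate herds) instead of fresh draws.
#' @param config A configuration list from [run_config()].
#' @return A data.frame with class `herd_deltas`, one row per
#'   herd x intervention.
#' @examples
#' d <- simulate_herds(n_herds = 2, n_cows = 20, seed = 1,
#'                     scenarios = "ovsynch")
#' d[, c("herd", "scenario", "d_cost", "d_ch4_per_l")]
#' @export
simulate_herds <- function(n_herds, n_cows = 200, seed = 1L,
                           scenarios = c("ovsynch", "ovsynch_p4", "double_pg"),
                           herd = NULL, config = sim_defaults()) {
  stopifnot(n_herds >= 1)
  rows <- vector("list", n_herds)
  for (i in seq_len(n_herds)) {
    hseed <- derive_seed(seed, c(1, i))
    if (is.null(herd)) {
      set.seed(derive_seed(seed, c(2, i)))
      h <- draw_herd_params(config)
    } else {
      h <- herd
    }
    res <- simulate_herd(h, n_cows, scenarios, hseed, config)
    base <- res$outcomes$baseline
    hp <- as.data.frame(unclass(h))
    rows[[i]] <- cbind(herd = i, hp, res$deltas,
                       baseline_ch4_per_l =
                         base$total_ch4_g / base$total_milk_l,
                       baseline_culls = base$culls,
                       anoestrous_at_vwp_end = base$anoestrous_at_vwp_end,
                       row.names = NULL)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("herd_deltas", "data.frame")
  out
}

delta_schema <- function() {
  c("herd", names(sim_defaults()$herd_ranges), "scenario",
    "d_cost", "d_cost_net", "d_ch4_per_l",
    "baseline_ch4_per_l", "baseline_culls", "anoestrous_at_vwp_end")
}

#' Write / read herd deltas as tidy CSV
#'
#' Round-trip safe: `read_deltas()` validates the column schema and errors
#' with the column difference on a mismatch, or with an explicit message on
#' an empty file.
#'
#' @param deltas A `herd_deltas` data.frame.
#' @param path File path.
#' @return `write_deltas()` returns the path invisibly; `read_deltas()` the
#'   validated data.frame.
#' @export
write_deltas <- function(deltas, path) {
  utils::write.csv(deltas, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_deltas
#' @export
read_deltas <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  if (nrow(out) == 0) stop("no herds in ", path, call. = FALSE)
  want <- delta_schema()
  if (!setequal(names(out), want)) {
    stop("delta file schema mismatch; missing: ",
         paste(setdiff(want, names(out)), collapse = ", "),
         "; unexpected: ",
         paste(setdiff(names(out), want), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("herd_deltas", "data.frame")
  out
}

#' Headline outcome for an average herd
#'
#' Simulates replicate herds with every input fixed (by default at the
#' means of the input distributions) and reports the mean cost saving per
#' cow per year net of drug cost, and the mean methane change per litre of
#' milk, each with a Monte-Carlo confidence interval over replicates.
#'
#' @param scenario Intervention to evaluate (default Ovsynch).
#' @param n_rep Number of replicate herds.
#' @param n_cows Cows per herd.
#' @param seed Master seed.
#' @param herd Fixed herd inputs (default: all inputs at their means).
#' @param conf Confidence level for the Monte-Carlo interval.
#' @param config A configuration list from [run_config()].
#' @return A list: `scenario`, `n_rep`, `mean_saving_net` (GBP/cow/year;
#'   positive = saving), `saving_ci`, `mean_d_ch4_per_l`, `ch4_ci`,
#'   `mean_baseline_ch4_per_l`, `pct_ch4_change`, and the per-replicate
#'   `deltas`.
#' @export
headline <- function(scenario = "ovsynch", n_rep = 500, n_cows = 200,
                     seed = 1L, herd = herd_params(config = config),
                     conf = 0.95, config = sim_defaults()) {
  d <- simulate_herds(n_rep, n_cows, seed, scenarios = scenario,
                      herd = herd, config = config)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  saving <- -d$d_cost_net
  ch4 <- d$d_ch4_per_l
  mci <- function(x) mean(x) + c(-1, 1) * zq * stats::sd(x) / sqrt(length(x))
  list(scenario = scenario, n_rep = n_rep, n_cows = n_cows,
       mean_saving_net = mean(saving), saving_ci = mci(saving),
       mean_d_ch4_per_l = mean(ch4), ch4_ci = mci(ch4),
       mean_baseline_ch4_per_l = mean(d$baseline_ch4_per_l),
       pct_ch4_change = 100 * mean(ch4) / mean(d$baseline_ch4_per_l),
       deltas = d)
}
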