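# Study orchestration: the (Vd2 x S) parameter sweep, per-run symbolic
# readouts, whole-brain summaries, and the focus-model statistics.

#' Default band/delay analysis conditions
#'
#' The three time-scale conditions of the study: broadband with delay 1
#' (fast/mixed dynamics), extended alpha band with delay 1 (alpha dynamics),
#' and broadband with delay 50 (slow dynamics).
#'
#' @return Tibble with columns `condition`, `low`, `high` (Hz), `tau`.
#' @export
default_conditions <- function() {
  tibble(
    condition = c("broadband_tau1", "alpha_tau1", "broadband_tau50"),
    low = c(0.5, 6, 0.5),
    high = c(70, 13, 70),
    tau = c(1L, 1L, 50L)
  )
}

#' Study configuration
#'
#' Bundles and validates everything that defines a sweep: the inhibitory
#' threshold grid, the coupling grid, runs per model, samples per run, the
#' band/delay conditions, the embedding dimension, and the seed scheme.
#'
#' @param vd2_grid Inhibitory threshold values (mV), default 6-8 step 0.5.
#' @param s_grid Coupling gain values, default 0-2 step 0.5.
#' @param runs_per_model Independent seeded runs per model (default 10).
#' @param samples_per_run Recorded samples per run (default 4096).
#' @param burn_in Discarded initial samples per run (default 1000).
#' @param conditions Tibble like [default_conditions()].
#' @param n_embed Ordinal embedding dimension (default 4).
#' @param base_seed Base of the per-cell seed scheme (see [cell_seed()]).
#' @param connectome Optional `connectome` object or path to a matrix file;
#'   if `NULL`, [run_study()] generates the default synthetic connectome
#'   seeded with `base_seed`.
#' @return A `study_config` object.
#' @export
study_config <- function(vd2_grid = seq(6, 8, by = 0.5),
                         s_grid = seq(0, 2, by = 0.5),
                         runs_per_model = 10,
                         samples_per_run = 4096,
                         burn_in = 1000,
                         conditions = default_conditions(),
                         n_embed = 4,
                         base_seed = 42,
                         connectome = NULL) {
  if (length(vd2_grid) < 1 || length(s_grid) < 1) {
    abort("parameter grids must be nonempty")
  }
  if (runs_per_model < 1) abort("`runs_per_model` must be at least 1")
  stopifnot(is.data.frame(conditions),
            all(c("condition", "low", "high", "tau") %in% names(conditions)))
  need <- (n_embed - 1) * max(conditions$tau) + 1
  if (samples_per_run < need) {
    abort(sprintf(
      "samples_per_run = %d too short for n = %d, max tau = %d (need >= %d)",
      samples_per_run, n_embed, max(conditions$tau), need
    ))
  }
  structure(
    list(
      vd2_grid = vd2_grid, s_grid = s_grid,
      runs_per_model = as.integer(runs_per_model),
      samples_per_run = as.integer(samples_per_run),
      burn_in = as.integer(burn_in),
      conditions = as_tibble(conditions),
      n_embed = as.integer(n_embed),
      base_seed = as.integer(base_seed),
      connectome = connectome
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "<study_config> %d vd2 x %d S models, %d runs x %d samples, %d conditions, base seed %d\n",
    length(x$vd2_grid), length(x$s_grid), x$runs_per_model,
    x$samples_per_run, nrow(x$conditions), x$base_seed
  ))
  invisible(x)
}

#' Deterministic per-cell seed
#'
#' Folds the base seed with the Vd2 index, S index and run index through a
#' multiplicative congruential hash (modulo 2^31 - 1), so each (model, run)
#' cell has an independent reproducible seed and any single cell can be
#' recomputed in isolation.
#'
#' @param base_seed Integer base seed.
#' @param i_vd2,i_s,run 1-based indices of the grid cell and run.
#' @return Integer seed below 2^31.
#' @export
cell_seed <- function(base_seed, i_vd2, i_s, run) {
  s <- as.numeric(base_seed) %% 2147483647
  for (k in c(i_vd2, i_s, run)) {
    s <- (s * 69069 + k) %% 2147483647
  }
  as.integer(s)
}

resolve_connectome <- function(config, connectome) {
  conn <- connectome %||% config$connectome
  if (is.null(conn)) {
    conn <- synthetic_connectome(seed = config$base_seed)
  } else if (is.character(conn)) {
    conn <- read_connectome(conn)
  }
  stopifnot(inherits(conn, "connectome"))
  conn
}

offdiag_mean <- function(m) {
  (sum(m) - sum(diag(m))) / (nrow(m) * (nrow(m) - 1))
}

#' Run the full parameter-sweep study
#'
#' For every (Vd2, S) cell of the grids, runs `runs_per_model` independent
#' seeded simulations, and for every band/delay condition computes the
#' per-run whole-brain permutation entropy, wsMI and JPE_inv (pairwise over
#' all regions). For the three focus models (low/balanced/high E-I at
#' `focus_s`), per-region profiles (PE and functional degree per measure,
#' per run) and run-averaged connectivity matrices are retained for the
#' regional statistics and the hub disruption index. Re-running with the
#' same configuration and connectome reproduces every table bitwise.
#'
#' @param config A [study_config()].
#' @param connectome Optional `connectome`; overrides `config$connectome`.
#' @param keep_matrices `"focus"` (default) keeps run-averaged connectivity
#'   matrices for the focus models, `"all"` for every model, `"none"` for
#'   none (disables [compare_focus_models()]).
#' @param focus_vd2 Named vector of the focus thresholds
#'   (default `c(low = 6.5, balanced = 7, high = 7.5)`).
#' @param focus_s Coupling value of the focus models (default 1).
#' @param verbose Print per-model progress.
#' @return A `study_result`: list of tibbles `whole_brain` (one row per
#'   model x run x condition), `rates` (one row per model x run), `regional`
#'   (focus models only), the retained `matrices`, and a `manifest` (config,
#'   connectome summary, per-cell seeds).
#' @export
run_study <- function(config, connectome = NULL,
                      keep_matrices = c("focus", "all", "none"),
                      focus_vd2 = c(low = 6.5, balanced = 7, high = 7.5),
                      focus_s = 1, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  keep_matrices <- match.arg(keep_matrices)
  conn <- resolve_connectome(config, connectome)
  conds <- config$conditions
  n_embed <- config$n_embed
  base_params <- nm_params(n_regions = conn$n_regions)
  fs <- 1 / base_params$dt

  wb <- rates <- regional <- list()
  mats <- list()
  seeds <- list()

  for (i_v in seq_along(config$vd2_grid)) {
    vd2 <- config$vd2_grid[i_v]
    for (i_s in seq_along(config$s_grid)) {
      s_val <- config$s_grid[i_s]
      is_focus <- any(abs(focus_vd2 - vd2) < 1e-9) &&
        abs(s_val - focus_s) < 1e-9
      keep_mat <- keep_matrices == "all" ||
        (keep_matrices == "focus" && is_focus)
      params <- nm_params(vd2 = vd2, s_couple = s_val,
                          n_regions = conn$n_regions)
      acc <- if (keep_mat) {
        lapply(stats::setNames(nm = conds$condition), function(cn)
          list(wsmi = 0, jpe_inv = 0))
      }
      if (verbose) {
        message(sprintf("model vd2=%.1f S=%.1f", vd2, s_val))
      }
      for (run in seq_len(config$runs_per_model)) {
        seed <- cell_seed(config$base_seed, i_v, i_s, run)
        seeds[[length(seeds) + 1L]] <-
          tibble(vd2 = vd2, s = s_val, run = run, seed = seed)
        sim <- simulate_network(params, conn,
                                n_samples = config$samples_per_run,
                                seed = seed, burn_in = config$burn_in)
        rates[[length(rates) + 1L]] <- tibble(
          vd2 = vd2, s = s_val, run = run,
          e_rate = mean(sim$e_rate), i_rate = mean(sim$i_rate),
          ei_ratio = ei_ratio(sim)
        )
        for (ci in seq_len(nrow(conds))) {
          cn <- conds$condition[ci]
          x <- bandpass(sim$eeg, fs, c(conds$low[ci], conds$high[ci]))
          S <- symbolize_matrix(x, n = n_embed, tau = conds$tau[ci])
          ps <- pairwise_symbolic(S, n_embed, vc_correction = TRUE)
          wb[[length(wb) + 1L]] <- tibble(
            vd2 = vd2, s = s_val, run = run, condition = cn,
            pe = mean(ps$pe),
            wsmi = offdiag_mean(ps$wsmi),
            jpe_inv = offdiag_mean(ps$jpe_inv)
          )
          if (is_focus) {
            nr <- conn$n_regions
            regional[[length(regional) + 1L]] <- tibble(
              vd2 = vd2, s = s_val, run = run, condition = cn,
              region = rep(conn$labels, 3L),
              metric = rep(c("pe", "degree_wsmi", "degree_jpe_inv"),
                           each = nr),
              value = c(ps$pe,
                        rowSums(ps$wsmi) / (nr - 1),
                        rowSums(ps$jpe_inv) / (nr - 1))
            )
          }
          if (keep_mat) {
            acc[[cn]]$wsmi <- acc[[cn]]$wsmi + ps$wsmi
            acc[[cn]]$jpe_inv <- acc[[cn]]$jpe_inv + ps$jpe_inv
          }
        }
      }
      if (keep_mat) {
        key <- sprintf("vd2=%.1f_s=%.1f", vd2, s_val)
        mats[[key]] <- lapply(acc, function(a) {
          lapply(a, function(m) {
            m <- m / config$runs_per_model
            dimnames(m) <- list(conn$labels, conn$labels)
            m
          })
        })
      }
    }
  }
  structure(
    list(
      whole_brain = list_rbind(wb),
      rates = list_rbind(rates),
      regional = if (length(regional)) list_rbind(regional) else NULL,
      matrices = mats,
      focus_vd2 = focus_vd2,
      focus_s = focus_s,
      manifest = list(
        config = config,
        n_regions = conn$n_regions,
        connectome_labels = conn$labels,
        seeds = list_rbind(seeds)
      )
    ),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cfg <- x$manifest$config
  cat(sprintf(
    "<study_result> %d models x %d runs x %d conditions on %d regions\n",
    length(cfg$vd2_grid) * length(cfg$s_grid), cfg$runs_per_model,
    nrow(cfg$conditions), x$manifest$n_regions
  ))
  invisible(x)
}

#' Whole-brain sweep summary
#'
#' Averages the per-run whole-brain values over runs, giving one value per
#' (condition, measure, Vd2, S) cell -- the tabular form of the sweep
#' heatmaps.
#'
#' @param sr A `study_result`.
#' @return Tibble with columns `condition`, `measure`
#'   (`pe`/`wsmi`/`jpe_inv`), `vd2`, `s`, `value`.
#' @export
summarize_whole_brain <- function(sr) {
  stopifnot(inherits(sr, "study_result"))
  sr$whole_brain |>
    group_by(.data$condition, .data$vd2, .data$s) |>
    summarise(across(c("pe", "wsmi", "jpe_inv"), mean), .groups = "drop") |>
    pivot_longer(c("pe", "wsmi", "jpe_inv"),
                 names_to = "measure", values_to = "value") |>
    select("condition", "measure", "vd2", "s", "value") |>
    arrange(.data$condition, .data$measure, .data$vd2, .data$s)
}

#' One Vd2-by-S heatmap table
#'
#' @param sr A `study_result`.
#' @param measure `"pe"`, `"wsmi"` or `"jpe_inv"`.
#' @param condition A condition label from the configuration.
#' @return Tibble: rows `vd2`, one column per `s` value.
#' @export
heatmap_table <- function(sr, measure, condition) {
  tab <- summarize_whole_brain(sr) |>
    filter(.data$measure == !!measure, .data$condition == !!condition)
  if (nrow(tab) == 0) {
    abort(sprintf("no cells for measure '%s', condition '%s'",
                  measure, condition))
  }
  tab |>
    select("vd2", "s", "value") |>
    pivot_wider(names_from = "s", values_from = "value", names_prefix = "s_")
}

#' E-I ratio table across the sweep
#'
#' Run-averaged excitatory and inhibitory rates per model, min-max
#' normalized across the whole sweep (the normalization constants are
#' returned as attributes `e_range` / `i_range`), with the E-I ratio
#' computed from raw rates (`ei_ratio`, run-averaged per-region
#' E/(E+I)) and from the normalized model-mean rates (`ei_ratio_norm`).
#'
#' @param sr A `study_result`.
#' @return Tibble with one row per (vd2, s) model.
#' @export
ei_ratio_table <- function(sr) {
  stopifnot(inherits(sr, "study_result"))
  tab <- sr$rates |>
    group_by(.data$vd2, .data$s) |>
    summarise(
      e_rate = mean(.data$e_rate), i_rate = mean(.data$i_rate),
      ei_ratio = mean(.data$ei_ratio), .groups = "drop"
    )
  e_range <- range(tab$e_rate)
  i_range <- range(tab$i_rate)
  norm <- function(x, r) if (diff(r) > 0) (x - r[1]) / diff(r) else x * 0
  tab <- tab |>
    mutate(
      e_norm = norm(.data$e_rate, e_range),
      i_norm = norm(.data$i_rate, i_range),
      ei_ratio_norm = ifelse(.data$e_norm + .data$i_norm > 0,
                             .data$e_norm / (.data$e_norm + .data$i_norm),
                             NA_real_)
    )
  attr(tab, "e_range") <- e_range
  attr(tab, "i_range") <- i_range
  tab
}

focus_cells <- function(sr) {
  list(
    low = c(vd2 = unname(sr$focus_vd2["low"]), s = sr$focus_s),
    balanced = c(vd2 = unname(sr$focus_vd2["balanced"]), s = sr$focus_s),
    high = c(vd2 = unname(sr$focus_vd2["high"]), s = sr$focus_s)
  )
}

mat_key <- function(cell) sprintf("vd2=%.1f_s=%.1f", cell["vd2"], cell["s"])

#' Focus-model statistics: t-tests, regional tests, hub disruption
#'
#' Compares the low-E-I and high-E-I focus models against the balanced
#' model: whole-brain independent t-tests with Cohen's d (sampling unit:
#' one whole-brain mean per run), per-region Mann-Whitney U tests with
#' two-stage FDR control at rate `q`, and the hub disruption index per
#' measure and condition (one OLS regression of degree change on balanced
#' degree per cell; 2 measures x conditions x comparisons).
#'
#' @param sr A `study_result` containing the focus models and their
#'   matrices (`keep_matrices` not `"none"`).
#' @param q Desired false discovery rate for the regional tests.
#' @return A `focus_comparison` list with tibbles `whole_brain`, `regional`
#'   and `hdi`.
#' @export
compare_focus_models <- function(sr, q = 0.01) {
  stopifnot(inherits(sr, "study_result"))
  cells <- focus_cells(sr)
  wbt <- sr$whole_brain
  have <- function(cell) any(abs(wbt$vd2 - cell["vd2"]) < 1e-9 &
                             abs(wbt$s - cell["s"]) < 1e-9)
  for (nm in names(cells)) {
    if (!have(cells[[nm]])) {
      abort(sprintf("focus model '%s' (vd2=%.1f, s=%.1f) missing from study",
                    nm, cells[[nm]]["vd2"], cells[[nm]]["s"]),
            class = "eidyn_error_missing_focus")
    }
  }
  conds <- sr$manifest$config$conditions$condition
  pull_wb <- function(cell, cond, meas) {
    wbt[abs(wbt$vd2 - cell["vd2"]) < 1e-9 & abs(wbt$s - cell["s"]) < 1e-9 &
          wbt$condition == cond, ][[meas]]
  }

  wb_rows <- expand_grid(
    comparison = c("low", "high"), condition = conds,
    measure = c("pe", "wsmi", "jpe_inv")
  ) |>
    purrr::pmap(function(comparison, condition, measure) {
      tibble(
        comparison = comparison, condition = condition, measure = measure,
        independent_t_test(
          pull_wb(cells[[comparison]], condition, measure),
          pull_wb(cells$balanced, condition, measure)
        )
      )
    }) |>
    list_rbind()

  reg_rows <- NULL
  if (!is.null(sr$regional)) {
    reg <- sr$regional
    reg_rows <- expand_grid(
      comparison = c("low", "high"), condition = conds,
      metric = unique(reg$metric)
    ) |>
      purrr::pmap(function(comparison, condition, metric) {
        cell <- cells[[comparison]]; bal <- cells$balanced
        sub_p <- reg[abs(reg$vd2 - cell["vd2"]) < 1e-9 &
                       reg$condition == condition & reg$metric == metric, ]
        sub_b <- reg[abs(reg$vd2 - bal["vd2"]) < 1e-9 &
                       reg$condition == condition & reg$metric == metric, ]
        regions <- unique(sub_p$region)
        res <- purrr::map(regions, function(rg) {
          mann_whitney_u(sub_p$value[sub_p$region == rg],
                         sub_b$value[sub_b$region == rg])
        }) |> list_rbind()
        tibble(comparison = comparison, condition = condition,
               metric = metric, region = regions,
               u = res$u, p_value = res$p_value,
               significant = fdr_bky(res$p_value, q = q))
      }) |>
      list_rbind()
  }

  hdi_rows <- NULL
  if (length(sr$matrices)) {
    hdi_rows <- expand_grid(
      comparison = c("low", "high"), condition = conds,
      measure = c("wsmi", "jpe_inv")
    ) |>
      purrr::pmap(function(comparison, condition, measure) {
        ref_m <- sr$matrices[[mat_key(cells$balanced)]][[condition]][[measure]]
        per_m <- sr$matrices[[mat_key(cells[[comparison]])]][[condition]][[measure]]
        h <- hub_disruption_index(functional_degree(ref_m)$degree,
                                  functional_degree(per_m)$degree)
        tibble(comparison = comparison, condition = condition,
               measure = measure,
               offset = h$offset, slope = h$slope, r_squared = h$r_squared,
               df_num = h$df_num, df_den = h$df_den, f_stat = h$f_stat,
               p_value = h$p_value)
      }) |>
      list_rbind()
  }

  structure(
    list(whole_brain = wb_rows, regional = reg_rows, hdi = hdi_rows),
    class = "focus_comparison"
  )
}

#' @export
print.focus_comparison <- function(x, ...) {
  cat("<focus_comparison>\n")
  if (!is.null(x$hdi)) {
    cat("hub disruption index:\n")
    print(as.data.frame(x$hdi[, c("comparison", "condition", "measure",
                                  "slope", "p_value")]), digits = 3)
  }
  invisible(x)
}
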