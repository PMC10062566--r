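#' Configure a simulation study
#'
#' Declarative description of the packaged simulation studies:
#' \describe{
#'   \item{A1}{isotropic free diffusion, net phase vs pulse duration
#'     (delta 10-50 ms, Delta = delta + 250 ms; expected zero phase).}
#'   \item{A2}{anisotropic free diffusion (ratio 0.5), net phase vs delta.}
#'   \item{A3}{anisotropic free diffusion, net phase vs ratio 0.1-0.9 at
#'     delta 20 ms, Delta 270 ms.}
#'   \item{B1}{cylinder-substrate walks, net phase and FA vs fibre density
#'     (200-500 cylinders), plus linear-gradient FA at three b-values.}
#'   \item{B2}{fixed substrate (500 cylinders), net phase and FA vs
#'     Delta 270-570 ms, linear-gradient FA at two b-values.}
#' }
#' Physical parameters follow the study conditions: gamma 2.6e8, D 2.3e-9
#' m^2/s, G2 25 T/m^2, and for B runs the Table of substrate parameters
#' (gamma-distributed radii, 501 um periodic box, extracellular spins).
#' The default ensemble sizes are reduced relative to the full studies
#' (`full = TRUE` restores N = 1e5/1.5e5, Ts = 1e3/2e3, 10 replicates).
#'
#' @param id One of `"A1"`, `"A2"`, `"A3"`, `"B1"`, `"B2"`, `"custom"`.
#' @param n_spins,n_steps Ensemble size and time steps per run.
#' @param replicates Independent trajectory sets per grid point.
#' @param seed Master seed; every run seed derives from it.
#' @param full Use the full-scale study sizes.
#' @param grid For `id = "custom"`: data.frame of grid columns
#'   (`delta_s`, `Delta_s`, `ratio`, `n_cylinders` as applicable).
#' @param gamma,G2,D_par Physical parameters (SI units).
#' @param bvalues_si b-values for the linear-gradient FA arm (SI, s m^-2);
#'   defaults per study.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(id = c("A1", "A2", "A3", "B1", "B2", "custom"),
                              n_spins = NULL, n_steps = NULL,
                              replicates = NULL, seed = 1L, full = FALSE,
                              grid = NULL, gamma = 2.6e8, G2 = 25,
                              D_par = 2.3e-9, bvalues_si = NULL) {
  id <- match.arg(id)
  is_b <- id %in% c("B1", "B2")
  n_spins <- n_spins %||% if (full) {if (is_b) 1.5e5 else 1e5} else
                          {if (is_b) 1e4 else 2e4}
  n_steps <- n_steps %||% if (full) {if (is_b) 2000L else 1000L} else 500L
  replicates <- replicates %||% if (full) 10L else 3L
  if (replicates < 1L) stop_invalid("'replicates' must be >= 1")
  grid <- switch(id,
    A1 = data.frame(delta_s = seq(0.010, 0.050, by = 0.010), ratio = 1),
    A2 = data.frame(delta_s = seq(0.010, 0.050, by = 0.010), ratio = 0.5),
    A3 = data.frame(delta_s = 0.020, Delta_s = 0.270,
                    ratio = seq(0.1, 0.9, by = 0.1)),
    B1 = data.frame(delta_s = 0.020, Delta_s = 0.270,
                    n_cylinders = seq(200L, 500L, by = 100L)),
    B2 = data.frame(delta_s = 0.020, Delta_s = seq(0.270, 0.570, by = 0.100),
                    n_cylinders = 500L),
    custom = grid
  )
  if (is.null(grid) || nrow(grid) == 0L) stop_invalid("empty parameter grid")
  if (is.null(grid$Delta_s)) grid$Delta_s <- grid$delta_s + 0.250
  bvalues_si <- bvalues_si %||%
    if (id == "B2") c(800, 1600) * 1e6 else c(576, 712, 1025) * 1e6
  structure(list(id = id, grid = grid, n_spins = as.integer(n_spins),
                 n_steps = as.integer(n_steps),
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 gamma = gamma, G2 = G2, D_par = D_par,
                 bvalues_si = bvalues_si, full = full),
            class = "experiment_config")
}

#' Run a simulation study
#'
#' Executes the configured grid with seeded replicates. Free-diffusion (A)
#' runs attach the analytic cylinder-symmetry prediction to every row;
#' substrate (B) runs attach the fibre density, the FA recovered from the
#' quadratic directional phases, and the FA from linear-gradient attenuation
#' at the configured b-values. One substrate is generated per grid point and
#' shared across its replicates (replicates differ in spin trajectories).
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print one line per grid point.
#' @return A `data.frame` (one row per grid point x replicate) with columns:
#'   grid parameters, `replicate`, `net_phase`, `net_phase_se`,
#'   `phi_x`, `phi_y`, `phi_z`, and per study `phase_analytic` (A) or
#'   `fibre_density`, `fa_quad`, `fa_lin`, `Dx`, `Dy`, `Dz` (B).
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  grid <- cfg$grid
  n_pts <- nrow(grid)
  seeds <- matrix(derive_seeds(cfg$seed, n_pts * (cfg$replicates + 1L)),
                  n_pts, cfg$replicates + 1L)
  field <- gradient_field("z2_3d", G2 = cfg$G2)
  is_b <- !is.null(grid$n_cylinders)
  rows <- vector("list", n_pts * cfg$replicates)
  for (g in seq_len(n_pts)) {
    timing <- pulse_timing(delta = grid$delta_s[g], Delta = grid$Delta_s[g])
    sub <- NULL
    if (is_b) {
      spec <- substrate_spec(n_cylinders = grid$n_cylinders[g],
                             seed = seeds[g, cfg$replicates + 1L])
      sub <- pack_cylinders(spec)
    }
    if (verbose)
      message(sprintf("[%s] grid point %d/%d", cfg$id, g, n_pts))
    for (rep in seq_len(cfg$replicates)) {
      run_seed <- seeds[g, rep]
      row <- tryCatch(
        run_single(cfg, grid[g, , drop = FALSE], timing, field, sub, run_seed),
        error = function(e) {
          warning(sprintf("grid point %d replicate %d failed: %s",
                          g, rep, conditionMessage(e)))
          NULL
        })
      if (!is.null(row)) {
        row$replicate <- rep
        rows[[(g - 1L) * cfg$replicates + rep]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  out
}

run_single <- function(cfg, gpt, timing, field, sub, run_seed) {
  if (is.null(sub)) {
    med <- medium_cylinder(cfg$D_par, gpt$ratio)
    traj <- walk_free(cfg$n_spins, cfg$n_steps, timing, med, seed = run_seed)
    origin <- c(0, 0, 0)
  } else {
    traj <- walk_restricted(cfg$n_spins, cfg$n_steps, timing, sub,
                            D = cfg$D_par, seed = run_seed)
    origin <- rep(sub$box_edge / 2, 3L)
  }
  acc <- accumulate_phases(traj, field, cfg$gamma, origin = origin)
  np <- net_phase(acc$phases)
  dirm <- colMeans(acc$directional)
  row <- data.frame(gpt, net_phase = np$net, net_phase_se = np$se,
                    phi_x = dirm[["x"]], phi_y = dirm[["y"]],
                    phi_z = dirm[["z"]])
  if (is.null(sub)) {
    row$phase_analytic <- phase_cylinder(cfg$gamma, cfg$G2, cfg$D_par,
                                         gpt$ratio, timing)
  } else {
    dq <- diffusivities_from_directional_phases(dirm[["x"]], dirm[["y"]],
                                                dirm[["z"]], cfg$gamma,
                                                cfg$G2, timing)
    d_lin <- vapply(c("x", "y", "z"), function(ax)
      attenuation_linear_gradient(traj, cfg$bvalues_si, ax,
                                  cfg$gamma)$D_apparent, numeric(1))
    row$fibre_density <- fibre_density(sub)
    row$Dx <- dq$Dx; row$Dy <- dq$Dy; row$Dz <- dq$Dz
    row$fa_quad <- fa(max(dq$Dx, 0), max(dq$Dy, 0), max(dq$Dz, 0))
    row$fa_lin <- fa(max(d_lin[["x"]], 0), max(d_lin[["y"]], 0),
                     max(d_lin[["z"]], 0))
  }
  row
}

#' Mean squared error of a study against its reference
#'
#' Averages, over grid points, the squared difference between the
#' replicate-mean simulated value and the reference: the analytic net-phase
#' prediction for free-diffusion (A) tables, or the linear-gradient FA for
#' substrate (B) tables.
#'
#' @param table A results table from [run_experiment()].
#' @param what `"net_phase"` (vs `phase_analytic`) or `"fa"`
#'   (`fa_quad` vs `fa_lin`); chosen automatically from the columns.
#' @return MSE (rad^2 for phases, dimensionless for FA).
#' @export
mse_vs_model <- function(table, what = NULL) {
  what <- what %||% if ("phase_analytic" %in% names(table)) "net_phase" else "fa"
  key_cols <- intersect(c("delta_s", "Delta_s", "ratio", "n_cylinders"),
                        names(table))
  key <- interaction(table[key_cols], drop = TRUE)
  if (what == "net_phase") {
    if (!"phase_analytic" %in% names(table))
      stop_invalid("table has no 'phase_analytic' reference column")
    sim <- tapply(table$net_phase, key, mean)
    ref <- tapply(table$phase_analytic, key, mean)
  } else {
    if (!all(c("fa_quad", "fa_lin") %in% names(table)))
      stop_invalid("table has no FA columns")
    sim <- tapply(table$fa_quad, key, mean)
    ref <- tapply(table$fa_lin, key, mean)
  }
  mean((sim - ref)^2)
}

#' Write a results table with its resolved configuration
#'
#' Writes the rows to CSV and the resolved configuration to a JSON sidecar
#' (`<stem>.json`).
#'
#' @param table A results table from [run_experiment()].
#' @param stem Output path stem (without extension).
#' @return The CSV path, invisibly.
#' @export
write_results <- function(table, stem) {
  csv <- paste0(stem, ".csv")
  write.csv(table, csv, row.names = FALSE)
  cfg <- attr(table, "config")
  if (!is.null(cfg)) {
    cfg$grid <- NULL
    jsonlite::write_json(unclass(cfg), paste0(stem, ".json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(csv)
}

#' Baseline-corrected mean phase of 1DFT line data
#'
#' The 1DFT readout yields complex lines (pixels along z, one line per
#' repetition); alternating lines with and without diffusion weighting give
#' a weighted and a baseline group. The mean phase over the masked pixels of
#' all lines is computed per group; the baseline mean is subtracted from the
#' weighted mean to remove phase changes not caused by the diffusion
#' gradients, and the standard errors are propagated
#' (`se = sqrt(se_w^2 + se_b^2)`).
#'
#' @param weighted,baseline Complex matrices, `n_pixels x n_lines`.
#' @param mask_weighted Logical vector over pixels selecting signal pixels
#'   of the weighted group.
#' @param mask_baseline Same for the baseline group (defaults to
#'   `mask_weighted`).
#' @return List with `mean_phase_diff` (rad), `se` (rad), and the per-group
#'   means and SEs.
#' @export
analyze_1dft_lines <- function(weighted, baseline,
                               mask_weighted, mask_baseline = mask_weighted) {
  stopifnot(is.matrix(weighted), is.matrix(baseline))
  if (nrow(weighted) != nrow(baseline))
    stop_invalid("weighted and baseline must have the same number of pixels")
  if (!any(mask_weighted) || !any(mask_baseline))
    stop_invalid("empty pixel mask")
  grp <- function(x, mask) {
    ph <- Arg(x[mask, , drop = FALSE])
    list(mean = mean(ph), se = sd(ph) / sqrt(length(ph)))
  }
  w <- grp(weighted, mask_weighted)
  b <- grp(baseline, mask_baseline)
  list(mean_phase_diff = w$mean - b$mean,
       se = sqrt(w$se^2 + b$se^2),
       weighted = w, baseline = b)
}

#' Synthesize 1DFT line data
#'
#' Builds a complex weighted/baseline line pair with a known diffusion phase
#' offset on the signal pixels plus Gaussian complex noise and an optional
#' common-mode phase drift across lines; used to exercise
#' [analyze_1dft_lines()].
#'
#' @param n_pixels,n_lines Matrix dimensions.
#' @param signal_pixels Indices of pixels carrying signal.
#' @param phase_offset True diffusion-induced phase on the weighted group,
#'   rad.
#' @param noise_sd Complex noise SD relative to unit signal.
#' @param drift Common-mode phase drift amplitude across lines, rad.
#' @param seed Optional integer seed.
#' @return List with `weighted`, `baseline` (complex matrices) and `mask`.
#' @export
synthesize_1dft_lines <- function(n_pixels = 16, n_lines = 512,
                                  signal_pixels = 5:12, phase_offset = 0.015,
                                  noise_sd = 0.05, drift = 0, seed = NULL) {
  maybe_with_seed(seed, {
    mask <- seq_len(n_pixels) %in% signal_pixels
    amp <- ifelse(mask, 1, 0.02)
    common <- drift * sin(seq(0, 2 * pi, length.out = n_lines))
    make <- function(extra_phase) {
      ph <- outer(rep(extra_phase, n_pixels), common, "+")
      sig <- amp * exp(1i * ph)
      noise <- matrix(complex(real = rnorm(n_pixels * n_lines, sd = noise_sd),
                              imaginary = rnorm(n_pixels * n_lines, sd = noise_sd)),
                      n_pixels, n_lines)
      sig + noise
    }
    list(weighted = make(phase_offset), baseline = make(0), mask = mask)
  })
}
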