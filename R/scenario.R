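#' Ground-truth kinetic scenario for a single-molecule condition
#'
#' A `kinetic_scenario` bundles every parameter needed to simulate one
#' experimental condition: binding kinetics, nucleotide-incorporation
#' kinetics, FRET geometry, and camera/photophysics settings. The shipped
#' condition fixtures (see [scenario_conditions()]) use published fitted
#' values as simulation ground truth so that recovery of those values
#' exercises the full analysis chain.
#'
#' @param condition_label Free-text label for the condition.
#' @param k_bind First-binding rate (s^-1). Arrival times of the polymerase
#'   at a DNA spot are exponential with this rate.
#' @param bound_fraction Fraction of molecules that ever bind (the plateau
#'   of the cumulative fraction-bound curve), in `[0, 1]`.
#' @param tau_dwell Mean bound dwell time (s). In the colocalization
#'   simulator every binding event has an exponential dwell with this mean;
#'   in the FRET simulator it is the residual dwell after the last
#'   incorporation, before dissociation.
#' @param t_incorporation Mean total nucleotide-incorporation time per
#'   productive binding (s); per-nucleotide waits are exponential with mean
#'   `t_incorporation / n_nucleotides`.
#' @param n_nucleotides Integer number of nucleotides incorporated per
#'   productive binding event.
#' @param e_start FRET efficiency at the moment of binding (unitless).
#' @param delta_e_per_nt FRET-efficiency decrease per incorporated
#'   nucleotide (unitless, 0.1 at the bench calibration).
#' @param frame_interval Seconds per excitation cycle (0.2 s: 200 ms
#'   alternating excitation; both emission channels share a cycle
#'   timestamp).
#' @param movie_length Movie duration in seconds.
#' @param photon_budget Mean total photons detected per frame from a bound
#'   donor-acceptor pair at E = 0 (i.e. donor fully unquenched).
#' @param background Mean background photons per frame and channel.
#' @param leakage Donor-to-acceptor-channel bleed-through fraction in
#'   `[0, 1)`.
#' @param direct_excitation Fraction of the acceptor-excitation signal that
#'   appears in the FRET channel under donor excitation, in `[0, 1)`.
#' @param gamma Detection/quantum-yield imbalance factor (> 0).
#' @param bleach_tau_donor,bleach_tau_acceptor Mean single-step
#'   photobleaching lifetimes (s) of the donor and acceptor dyes.
#' @param n_molecules Number of molecules (DNA spots) to simulate.
#' @param seed Integer seed; identical scenario + seed gives identical
#'   simulations.
#'
#' @return An object of class `kinetic_scenario` (a validated named list).
#' @seealso [simulate_colocalization()], [simulate_fret()],
#'   [read_scenario()], [scenario_conditions()]
#' @export
#' @examples
#' sc <- kinetic_scenario(k_bind = 0.03, bound_fraction = 0.71,
#'                        tau_dwell = 2.7, n_molecules = 20, seed = 1)
#' sc$k_bind
kinetic_scenario <- function(condition_label = "condition",
                             k_bind = 0.03,
                             bound_fraction = 0.71,
                             tau_dwell = 2.7,
                             t_incorporation = 4.7,
                             n_nucleotides = 4L,
                             e_start = 0.6,
                             delta_e_per_nt = 0.1,
                             frame_interval = 0.2,
                             movie_length = 180,
                             photon_budget = 500,
                             background = 10,
                             leakage = 0.1,
                             direct_excitation = 0.05,
                             gamma = 1.2,
                             bleach_tau_donor = 600,
                             bleach_tau_acceptor = 600,
                             n_molecules = 100L,
                             seed = 1L) {
  sc <- list(
    condition_label = as.character(condition_label),
    k_bind = as.numeric(k_bind),
    bound_fraction = as.numeric(bound_fraction),
    tau_dwell = as.numeric(tau_dwell),
    t_incorporation = as.numeric(t_incorporation),
    n_nucleotides = as.integer(n_nucleotides),
    e_start = as.numeric(e_start),
    delta_e_per_nt = as.numeric(delta_e_per_nt),
    frame_interval = as.numeric(frame_interval),
    movie_length = as.numeric(movie_length),
    photon_budget = as.numeric(photon_budget),
    background = as.numeric(background),
    leakage = as.numeric(leakage),
    direct_excitation = as.numeric(direct_excitation),
    gamma = as.numeric(gamma),
    bleach_tau_donor = as.numeric(bleach_tau_donor),
    bleach_tau_acceptor = as.numeric(bleach_tau_acceptor),
    n_molecules = as.integer(n_molecules),
    seed = as.integer(seed)
  )
  class(sc) <- "kinetic_scenario"
  validate_scenario(sc)
}

#' Validate a kinetic scenario
#'
#' Checks the internal consistency of a [kinetic_scenario()]: positive
#' rates and lifetimes, fractions in range, and that the FRET staircase
#' stays strictly positive (`e_start - n_nucleotides * delta_e_per_nt > 0`).
#'
#' @param sc A `kinetic_scenario`.
#' @return `sc`, invisibly unchanged, or an error of class
#'   `smkinetics_invalid`.
#' @export
validate_scenario <- function(sc) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop_invalid(msg)
  chk(inherits(sc, "kinetic_scenario"), "not a kinetic_scenario")
  chk(sc$k_bind >= 0, "k_bind must be >= 0")
  chk(sc$bound_fraction >= 0 && sc$bound_fraction <= 1,
      "bound_fraction must be in [0, 1]")
  chk(sc$tau_dwell > 0, "tau_dwell must be > 0")
  chk(sc$t_incorporation > 0, "t_incorporation must be > 0")
  chk(sc$n_nucleotides >= 0, "n_nucleotides must be >= 0")
  chk(sc$e_start > 0 && sc$e_start <= 1, "e_start must be in (0, 1]")
  chk(sc$delta_e_per_nt >= 0, "delta_e_per_nt must be >= 0")
  chk(sc$e_start - sc$n_nucleotides * sc$delta_e_per_nt > 0,
      "final FRET level must stay positive: n_nucleotides * delta_e_per_nt < e_start")
  chk(sc$frame_interval > 0, "frame_interval must be > 0")
  chk(sc$movie_length > 0, "movie_length must be > 0")
  chk(sc$photon_budget > 0, "photon_budget must be > 0")
  chk(sc$background >= 0, "background must be >= 0")
  chk(sc$leakage >= 0 && sc$leakage < 1, "leakage must be in [0, 1)")
  chk(sc$direct_excitation >= 0 && sc$direct_excitation < 1,
      "direct_excitation must be in [0, 1)")
  chk(sc$gamma > 0, "gamma must be > 0")
  chk(sc$bleach_tau_donor > 0 && sc$bleach_tau_acceptor > 0,
      "bleach lifetimes must be > 0")
  chk(sc$n_molecules > 0, "n_molecules must be > 0")
  invisible(sc)
}

#' @export
print.kinetic_scenario <- function(x, ...) {
  cat("<kinetic_scenario> ", x$condition_label, "\n", sep = "")
  cat(sprintf("  binding: k = %.3g /s, bound fraction = %.2f, dwell = %.2f s\n",
              x$k_bind, x$bound_fraction, x$tau_dwell))
  cat(sprintf("  incorporation: %d nt in %.2f s, E %.2f - %d x %.2f\n",
              x$n_nucleotides, x$t_incorporation, x$e_start,
              x$n_nucleotides, x$delta_e_per_nt))
  cat(sprintf("  camera: %.3g s frames, %.0f s movie, budget %.0f, bg %.0f\n",
              x$frame_interval, x$movie_length, x$photon_budget, x$background))
  cat(sprintf("  photophysics: l = %.2f, d = %.2f, gamma = %.2f, bleach %.0f/%.0f s\n",
              x$leakage, x$direct_excitation, x$gamma,
              x$bleach_tau_donor, x$bleach_tau_acceptor))
  cat(sprintf("  %d molecules, seed %d\n", x$n_molecules, x$seed))
  invisible(x)
}

#' Read or write a scenario file
#'
#' Scenarios are stored as flat YAML, one file per experimental condition.
#' Unknown keys are rejected so that typos in a config do not silently
#' fall back to defaults.
#'
#' @param path Path to a YAML scenario file.
#' @return `read_scenario()` returns a validated [kinetic_scenario()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_invalid(paste0("scenario file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(kinetic_scenario))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    stop_invalid(paste0("unknown scenario fields: ", paste(extra, collapse = ", ")))
  }
  do.call(kinetic_scenario, vals)
}

#' @param sc A `kinetic_scenario` to serialize.
#' @rdname read_scenario
#' @export
write_scenario <- function(sc, path) {
  validate_scenario(sc)
  yaml::write_yaml(unclass(sc), path)
  invisible(path)
}

#' Shipped condition fixtures
#'
#' The package ships one scenario file per experimental condition, with the
#' published fitted kinetics of that condition used as simulation ground
#' truth: colocalization conditions (binding rate, bound fraction, bound
#' dwell) for polymerase alone, with Ku, and for the BRCT-interface double
#' mutant; FRET incorporation conditions (total incorporation time, four
#' nucleotides at 0.1 E per step from 0.6) for polymerase alone, with Ku,
#' and for the isolated catalytic domain.
#'
#' @param condition Optional condition name; omit to list available names.
#' @return A character vector of names, or a [kinetic_scenario()].
#' @export
#' @examples
#' scenario_conditions()
#' sc <- scenario_conditions("fret_pol_ku")
scenario_conditions <- function(condition = NULL) {
  dir <- system.file("extdata", "scenarios", package = "smkinetics")
  files <- list.files(dir, pattern = "\\.yaml$")
  names <- sub("\\.yaml$", "", files)
  if (is.null(condition)) {
    return(sort(names))
  }
  if (!condition %in% names) {
    stop_invalid(paste0("unknown condition '", condition, "'; available: ",
                        paste(sort(names), collapse = ", ")))
  }
  read_scenario(file.path(dir, paste0(condition, ".yaml")))
}
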