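# The protein-DNA energy model contract: any object with an `energy_score`
# method returning a finite scalar (lower = more stable) for a homeodomain
# peptide and a DNA core sequence can drive the in silico evolution engine.
# Atomic scoring backends (homology modelling + physics-based potentials)
# plug in through `function_energy_model()`.

#' Score a protein-DNA complex under an energy model
#'
#' Generic entry point of the energy-model contract used by the in silico
#' evolution engine. Implementations must be deterministic given the model's
#' own parameters, return a finite scalar, and follow the convention that
#' lower energies mean more stable complexes.
#'
#' @param model an energy model object.
#' @param protein homeodomain amino-acid string (typically 60 residues).
#' @param dna DNA core string or [dna_core()] object.
#' @param ... passed to methods.
#' @return A numeric scalar energy.
#' @export
energy_score <- function(model, protein, dna, ...) UseMethod("energy_score")

#' @export
energy_score.default <- function(model, protein, dna, ...)
  stop("no energy_score method for class ", paste(class(model), collapse = "/"))

#' Model descriptor string
#' @param model an energy model.
#' @return A single character string naming the model and its parameters.
#' @export
model_descriptor <- function(model) UseMethod("model_descriptor")

#' @export
model_descriptor.default <- function(model) paste(class(model)[1])

#' Wrap an arbitrary scoring function as an energy model
#'
#' Adapter for external scoring backends: any function
#' `(protein, dna_string) -> energy` satisfies the contract through this
#' wrapper. A subprocess-based atomic backend (e.g. a structure-modelling
#' score exposed as a command-line tool) can be wrapped the same way by
#' having the function call the tool and parse its scalar output.
#'
#' @param fn function of `(protein, dna)` returning a finite numeric scalar.
#' @param descriptor short name describing the backend.
#' @return An object of class `function_energy_model`.
#' @export
function_energy_model <- function(fn, descriptor = "user_function") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, descriptor = descriptor),
            class = c("function_energy_model", "energy_model"))
}

#' @export
energy_score.function_energy_model <- function(model, protein, dna, ...) {
  dna <- as_core_string(dna)
  e <- model$fn(protein, dna)
  if (!is.numeric(e) || length(e) != 1L) stop("backend did not return a scalar energy")
  e
}

#' @export
model_descriptor.function_energy_model <- function(model) model$descriptor

#' Planted-optimum energy model
#'
#' A synthetic energy landscape with a known global minimum: the energy of a
#' DNA core is `mismatch_penalty` times its Hamming distance to
#' `target_site`, plus optional Gaussian roughness (deterministic per
#' sequence, derived from a sequence hash). With `noise_sd = 0` the unique
#' global minimum is the target itself, which makes the model an exact oracle
#' for the evolution engine.
#'
#' @param target_site DNA string over ACGT; its length defines the core length.
#' @param mismatch_penalty energy units per mismatching position (> 0).
#' @param noise_sd standard deviation of the per-sequence energy roughness.
#' @return An object of class `planted_energy_model`.
#' @export
planted_energy_model <- function(target_site, mismatch_penalty = 1, noise_sd = 0) {
  stopifnot(grepl("^[ACGT]+$", target_site), mismatch_penalty > 0, noise_sd >= 0)
  structure(list(target = target_site, penalty = mismatch_penalty, noise_sd = noise_sd),
            class = c("planted_energy_model", "energy_model"))
}

#' @export
energy_score.planted_energy_model <- function(model, protein, dna, ...) {
  dna <- as_core_string(dna)
  if (nchar(dna) != nchar(model$target))
    stop("core length ", nchar(dna), " does not match target length ",
         nchar(model$target))
  mism <- sum(strsplit(dna, "")[[1]] != strsplit(model$target, "")[[1]])
  e <- mism * model$penalty
  if (model$noise_sd > 0) {
    # deterministic roughness: seed derived from the sequence itself
    h <- sum(utf8ToInt(dna) * seq_len(nchar(dna))) %% .Machine$integer.max
    e <- e + with_seed(h, rnorm(1, 0, model$noise_sd))
  }
  e
}

#' @export
model_descriptor.planted_energy_model <- function(model)
  sprintf("planted_optimum(target=%s, penalty=%g, noise_sd=%g)",
          model$target, model$penalty, model$noise_sd)

#' Built-in contact-potential energy model
#'
#' A coarse statistical potential for homeodomain-DNA recognition. The model
#' holds a contact map - pairs of (homeodomain position, DNA core position)
#' with weights emulating the recognition-helix (helix 3) and N-terminal-arm
#' contacts seen in homeodomain-DNA co-crystal structures - and a 20 x 4
#' residue-base compatibility table. The energy of a complex is
#' `-sum(weight * compat[residue, base])` over the contact map, so the model
#' is additive over DNA positions and exact position-wise optimisation is
#' possible. It is a deliberately simple stand-alone potential for testing
#' the evolution machinery, not a predictor of in vivo binding sites.
#'
#' The default contact map places the strongest contacts between helix-3
#' residues (homeodomain positions 47, 50, 51, 54) and the centre of the
#' 11-bp core, with lighter N-terminal-arm contacts (positions 3 and 5) to
#' the core's 5' half. The default compatibility table encodes well-known
#' preferences (e.g. asparagine-adenine, glutamine-adenine/thymine,
#' arginine/lysine-guanine, hydrophobic residue-thymine) over a small
#' uniform baseline.
#'
#' @param contact_map data.frame with columns `hd_pos` (1-60), `core_pos`
#'   (1-based core position) and `weight` (> 0); `NULL` for the default map.
#' @param compat 20 x 4 numeric matrix (rows = amino acids in
#'   `ACDEFGHIKLMNPQRSTVWY` order, columns = A,C,G,T); `NULL` for the default.
#' @param core_length DNA core length the map addresses (default 11).
#' @return An object of class `contact_potential_model`.
#' @export
contact_potential_model <- function(contact_map = NULL, compat = NULL,
                                    core_length = 11L) {
  if (is.null(compat)) compat <- default_compat_table()
  stopifnot(is.matrix(compat), nrow(compat) == 20L, ncol(compat) == 4L)
  rownames(compat) <- AA_ALPHABET
  colnames(compat) <- DNA_BASES
  if (is.null(contact_map)) contact_map <- default_contact_map(core_length)
  stopifnot(all(c("hd_pos", "core_pos", "weight") %in% names(contact_map)),
            all(contact_map$weight > 0),
            all(contact_map$core_pos >= 1), all(contact_map$core_pos <= core_length),
            all(contact_map$hd_pos >= 1), all(contact_map$hd_pos <= 60))
  structure(list(contact_map = contact_map, compat = compat,
                 core_length = as.integer(core_length)),
            class = c("contact_potential_model", "energy_model"))
}

# residue-base compatibility scores in [0, 1]; larger = more favourable
default_compat_table <- function() {
  m <- matrix(0.05, 20, 4, dimnames = list(AA_ALPHABET, DNA_BASES))
  m["N", "A"] <- 1.00            # Asn51-adenine pair of the ATTA core
  m["Q", "A"] <- 0.80; m["Q", "T"] <- 0.55
  m["R", "G"] <- 0.90; m["R", "A"] <- 0.30
  m["K", "G"] <- 0.75; m["K", "T"] <- 0.25
  m["I", "T"] <- 0.70; m["V", "T"] <- 0.60; m["M", "T"] <- 0.55
  m["T", "T"] <- 0.35; m["S", "C"] <- 0.30; m["S", "A"] <- 0.25
  m["W", "T"] <- 0.45; m["Y", "T"] <- 0.40; m["H", "G"] <- 0.50
  m["E", "C"] <- 0.35; m["D", "C"] <- 0.30
  m
}

# helix-3 + N-terminal-arm contact geometry, scaled to an arbitrary core
default_contact_map <- function(core_length = 11L) {
  centre <- as.integer(ceiling(core_length / 2))
  clamp <- function(p) pmin(pmax(p, 1L), core_length)
  data.frame(
    hd_pos  = c(47L, 50L, 50L, 51L, 51L, 54L, 54L, 3L, 5L, 5L),
    core_pos = clamp(c(centre - 1L, centre, centre + 1L, centre, centre + 2L,
                       centre + 1L, centre + 3L, centre - 3L, centre - 2L,
                       centre - 4L)),
    weight  = c(1.0, 1.2, 0.8, 1.5, 0.9, 1.0, 0.6, 0.7, 0.8, 0.5)
  )
}

#' @export
energy_score.contact_potential_model <- function(model, protein, dna, ...) {
  dna <- as_core_string(dna)
  if (nchar(dna) != model$core_length)
    stop("core length ", nchar(dna), " does not match model core_length ",
         model$core_length)
  if (nchar(protein) < max(model$contact_map$hd_pos))
    stop("protein shorter than the highest contacted homeodomain position")
  res <- strsplit(protein, "")[[1]][model$contact_map$hd_pos]
  base <- strsplit(dna, "")[[1]][model$contact_map$core_pos]
  ok <- res %in% AA_ALPHABET & base %in% DNA_BASES
  -sum(model$contact_map$weight[ok] * model$compat[cbind(res[ok], base[ok])])
}

#' @export
model_descriptor.contact_potential_model <- function(model)
  sprintf("contact_potential(core_length=%d, contacts=%d)",
          model$core_length, nrow(model$contact_map))
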