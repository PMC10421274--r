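# Synthetic fixture generation: labeled SMILES datasets with a planted
# association between intramolecular hydrogen-bond capability and activity,
# in the ChEMBL CSV dialect, so the whole stack is testable offline.

#' Specification for a synthetic bioactivity fixture
#'
#' @param n_molecules Number of distinct base compounds (>= 4).
#' @param active_fraction Fraction of compounds drawn from the
#'   hydrogen-bond-capable template family (family A).
#' @param hbond_signal_strength Probability that a family-A compound is
#'   assigned the active label (and a family-B compound the inactive
#'   label).
#' @param seed RNG seed for the whole generation process.
#' @param noise Probability of flipping the assigned label.
#' @param n_missing Extra rows with a blank IC50 (exercise the
#'   missing-value rule).
#' @param n_duplicates Extra rows duplicating existing compounds (exercise
#'   deduplication).
#' @param n_salts Extra compounds written as dot-disconnected salts
#'   (exercise salt stripping).
#' @param n_intermediate Extra compounds with IC50 in the intermediate band
#'   (exercise intermediate exclusion).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 200L, active_fraction = 0.5,
                         hbond_signal_strength = 0.9, seed = 7L,
                         noise = 0.1, n_missing = 0L, n_duplicates = 0L,
                         n_salts = 0L, n_intermediate = 0L) {
  stopifnot(n_molecules >= 4L,
            active_fraction >= 0, active_fraction <= 1,
            hbond_signal_strength >= 0, hbond_signal_strength <= 1,
            noise >= 0, noise <= 1,
            n_missing >= 0, n_duplicates >= 0, n_salts >= 0,
            n_intermediate >= 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 active_fraction = active_fraction,
                 hbond_signal_strength = hbond_signal_strength,
                 seed = as.integer(seed), noise = noise,
                 n_missing = as.integer(n_missing),
                 n_duplicates = as.integer(n_duplicates),
                 n_salts = as.integer(n_salts),
                 n_intermediate = as.integer(n_intermediate)),
            class = "fixture_spec")
}

# deterministic draw of n templates from a family pool (no replacement)
.draw_pool <- function(pool, n, what) {
  if (n > length(pool)) {
    stop("fixture requests ", n, " ", what, " compounds but only ",
         length(pool), " verified templates exist", call. = FALSE)
  }
  sample(pool, n)
}

#' Generate the fixture molecule pool
#'
#' Draws `n_molecules` distinct SMILES deterministically under the fixture
#' specification's seed: a fraction `active_fraction` from family A (scaffolds with an
#' ortho donor/acceptor pair whose default-seed conformer shows an
#' intramolecular hydrogen bond) and the rest from family B (matched
#' donor-free analogues, zero hydrogen-bond triples).
#'
#' @param spec A [fixture_spec()].
#' @return A data frame with columns `smiles` and `family`
#'   (`"A"`/`"B"`).
#' @export
generate_molecule_pool <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n_a <- round(spec$n_molecules * spec$active_fraction)
  n_b <- spec$n_molecules - n_a
  data.frame(smiles = c(.draw_pool(.FAMILY_A, n_a, "family-A"),
                        .draw_pool(.FAMILY_B, n_b, "family-B")),
             family = rep(c("A", "B"), c(n_a, n_b)),
             stringsAsFactors = FALSE)
}

.log_uniform <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

#' Generate a synthetic bioactivity table
#'
#' Assigns labels by scaffold family (family A is labeled active with
#' probability `hbond_signal_strength`, family B inactive with the same
#' probability), flips labels with probability `noise`, then samples IC50
#' values log-uniformly inside the label's band, keeping a 5% margin from
#' the 1000/10000 nM boundaries so labels are unambiguous. Planted defect
#' rows (missing IC50, duplicates, salts, intermediates) are appended from
#' extra pool templates and the table is shuffled deterministically.
#'
#' @param spec A [fixture_spec()].
#' @return A data frame in the ChEMBL dialect (`molecule_chembl_id`,
#'   `canonical_smiles`, `standard_value`, `standard_units`); the
#'   generation ground truth (base compounds with family and intended
#'   label) is in the `"truth"` attribute.
#' @export
generate_bioactivity_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  pool <- generate_molecule_pool(spec)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1L)

  lab <- ifelse(pool$family == "A", "active", "inactive")
  keep_signal <- stats::runif(nrow(pool)) <= spec$hbond_signal_strength
  lab[!keep_signal] <- ifelse(lab[!keep_signal] == "active",
                              "inactive", "active")
  flip <- stats::runif(nrow(pool)) < spec$noise
  lab[flip] <- ifelse(lab[flip] == "active", "inactive", "active")
  ic50 <- ifelse(lab == "active",
                 .log_uniform(nrow(pool), 10, 950),
                 .log_uniform(nrow(pool), 10500, 1e6))
  main <- data.frame(canonical_smiles = pool$smiles,
                     standard_value = ic50,
                     stringsAsFactors = FALSE)
  truth <- data.frame(smiles = pool$smiles, family = pool$family,
                      label = lab, stringsAsFactors = FALSE)

  # extra templates, disjoint from the main body, for the planted defects
  spare <- setdiff(c(.FAMILY_A, .FAMILY_B), pool$smiles)
  need <- spec$n_missing + spec$n_salts + spec$n_intermediate
  if (need > length(spare)) {
    stop("not enough spare templates for the requested defect rows",
         call. = FALSE)
  }
  spare <- sample(spare, need)
  take <- function(k) {
    out <- spare[seq_len(k)]
    spare <<- spare[-seq_len(k)]
    out
  }
  extras <- list()
  if (spec$n_missing > 0L) {
    extras$missing <- data.frame(canonical_smiles = take(spec$n_missing),
                                 standard_value = NA_real_)
  }
  if (spec$n_salts > 0L) {
    counter_ions <- c("Cl", "[Na+].[Cl-]", "O=S(=O)(O)O")
    extras$salts <- data.frame(
      canonical_smiles = paste(take(spec$n_salts),
                               rep_len(counter_ions, spec$n_salts),
                               sep = "."),
      standard_value = .log_uniform(spec$n_salts, 10, 950))
  }
  if (spec$n_intermediate > 0L) {
    extras$intermediate <- data.frame(
      canonical_smiles = take(spec$n_intermediate),
      standard_value = .log_uniform(spec$n_intermediate, 1100, 9500))
  }
  if (spec$n_duplicates > 0L) {
    idx <- sample.int(nrow(main), spec$n_duplicates, replace = FALSE)
    extras$duplicates <- main[idx, , drop = FALSE]
  }
  out <- rbind(main, do.call(rbind, unname(extras)))
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out <- data.frame(molecule_chembl_id = sprintf("FIX%04d", seq_len(nrow(out))),
                    out, standard_units = "nM", stringsAsFactors = FALSE)
  attr(out, "truth") <- truth
  out
}

#' Write a synthetic bioactivity fixture CSV
#'
#' @param spec A [fixture_spec()].
#' @param path Output CSV path.
#' @return `path`, invisibly; the table's `"truth"` attribute is attached
#'   to the return value's `"truth"` attribute.
#' @export
generate_bioactivity_csv <- function(spec, path) {
  tab <- generate_bioactivity_table(spec)
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  out <- path
  attr(out, "truth") <- attr(tab, "truth")
  invisible(out)
}
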