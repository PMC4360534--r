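#' Pipeline configuration
#'
#' All tunable parameters of the complex pipeline with their default
#' values: genome pairing cap (`max_nt` 10000), gap-column threshold
#' (0.8), identity clustering threshold (0.8), PLM regularization and
#' optimizer settings, contact/classification thresholds (0.8 / 0.75),
#' sequence-sufficiency minimum (0.3), evaluation distance cutoffs
#' (5/8/10/12 Angstrom), restraint parameters (5.0/2.0/2.0) and the
#' alphabet size. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return An object of class `ev_config` (a validated named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    max_nt = 10000L,
    max_gap_fraction = 0.8,
    identity_threshold = 0.8,
    lambda_h = 0.01,
    lambda_J = NULL,
    tol = 1e-4,
    max_iter = 500L,
    contact_threshold = 0.8,
    weak_lower = 0.75,
    sufficiency_min = 0.3,
    distance_cutoffs = c(5, 8, 10, 12),
    restraint_d_eff = 5.0,
    restraint_lower = 2.0,
    restraint_upper = 2.0,
    alphabet_q = 21L,
    apc = TRUE,
    exclude_gap = TRUE,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  stopifnot(cfg$max_nt > 0, cfg$max_gap_fraction > 0,
            cfg$max_gap_fraction <= 1, cfg$identity_threshold > 0,
            cfg$identity_threshold <= 1, cfg$lambda_h > 0,
            cfg$weak_lower <= cfg$contact_threshold,
            cfg$sufficiency_min > 0, cfg$alphabet_q >= 2)
  structure(cfg, class = "ev_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of configuration keys; unknown keys are
#'   rejected.
#' @return An `ev_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

config_scoring <- function(cfg) {
  scoring_config(contact_threshold = cfg$contact_threshold,
                 weak_lower = cfg$weak_lower,
                 sufficiency_min = cfg$sufficiency_min)
}

#' Machine-readable provenance record
#'
#' Hash of the effective configuration, package version and seed,
#' emitted with every pipeline run.
#'
#' @param config An `ev_config`.
#' @return A list (config_hash, package_version, r_version, seed).
#' @export
provenance_record <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  list(config_hash = unname(tools::md5sum(tmp)),
       package_version =
         as.character(utils::packageVersion("evcomplexr")),
       r_version = as.character(getRversion()),
       seed = config$seed)
}

#' Run the full complex pipeline in memory
#'
#' Pairs homologs by genomic proximity, concatenates, filters gap
#' columns, reweights sequences, fits the Potts model by
#' pseudolikelihood maximization, reduces it to APC-corrected coupling
#' scores, and converts the inter-protein block into ranked EVcomplex
#' scores, selected contacts and a subunit interaction call.
#'
#' When the alignment fails the sequence-sufficiency filter
#' (`N_eff / L <= sufficiency_min`), a warning is raised and the
#' pipeline stops after preprocessing unless `override_sufficiency` is
#' set — low-depth alignments are exactly the regime in which the score
#' normalization matters, so the gate is soft.
#'
#' @param aln_a,aln_b Per-protein `ev_alignment` objects.
#' @param loci_a,loci_b Gene-location data.frames.
#' @param config An [pipeline_config()].
#' @param override_sufficiency Continue despite a failed sufficiency
#'   check (default FALSE).
#' @param pair_id Label for the subunit pair.
#' @return An object of class `ev_result` with elements `status`
#'   (`"ok"` or `"insufficient"`), `pairs`, `report`, `weights`,
#'   `sufficiency`, and on success `model`, `couplings_raw`, `couplings`,
#'   `predictions`, `contacts`, `call`, `edge_list`, `provenance`.
#' @export
complex_pipeline <- function(aln_a, aln_b, loci_a, loci_b,
                             config = pipeline_config(),
                             override_sufficiency = FALSE,
                             pair_id = "A:B") {
  pairs <- match_pairs(loci_a, loci_b, max_nt = config$max_nt)
  concat <- concatenate_alignments(aln_a, aln_b, pairs)
  pre <- preprocess_concat(concat,
                           max_gap_fraction = config$max_gap_fraction,
                           identity_threshold = config$identity_threshold)
  ok <- sufficiency_check(pre$report$n_eff, pre$report$length_total,
                          config$sufficiency_min)
  res <- list(status = "ok", pair_id = pair_id, pairs = pairs,
              concat = pre$concat, weights = pre$weights,
              report = pre$report, sufficiency = ok,
              provenance = provenance_record(config))
  if (!ok) {
    warning(sprintf(
      paste0("sequence sufficiency not met: N_eff/L = %.3f <= %.2f; ",
             "predictions from this alignment are unreliable%s"),
      pre$report$neff_per_l, config$sufficiency_min,
      if (override_sufficiency) " (override in effect, continuing)"
      else ""))
    if (!override_sufficiency) {
      res$status <- "insufficient"
      class(res) <- "ev_result"
      return(res)
    }
  }
  enc <- encode_alignment(pre$concat, aa_alphabet(config$alphabet_q))
  model <- fit_plm(enc, pre$weights, lambda_h = config$lambda_h,
                   lambda_J = config$lambda_J, tol = config$tol,
                   max_iter = config$max_iter, q = config$alphabet_q)
  raw <- coupling_scores(model, boundary = pre$concat$boundary,
                         exclude_gap = config$exclude_gap)
  corrected <- if (isTRUE(config$apc)) apply_apc(raw) else raw
  preds <- inter_couplings(corrected, pre$concat$column_maps)
  preds <- raw_reliability(preds)
  preds <- evcomplex_scores(preds, pre$report$n_eff,
                            pre$report$length_total)
  sc <- config_scoring(config)
  res$model <- model
  res$couplings_raw <- raw
  res$couplings <- corrected
  res$predictions <- preds
  res$contacts <- select_contacts(preds, sc)
  res$call <- classify_interaction(max(preds$evcomplex_score), sc,
                                   pair_id = pair_id)
  res$edge_list <- coupling_edge_list(raw, corrected,
                                      pre$concat$column_maps)
  class(res) <- "ev_result"
  res
}

#' @export
print.ev_result <- function(x, ...) {
  cat(sprintf("ev_result [%s]: status %s, N = %d, N_eff/L = %.3f\n",
              x$pair_id, x$status, x$report$n_sequences,
              x$report$neff_per_l))
  if (x$status == "ok") {
    cat(sprintf("  %d contacts at threshold; call: %s (best %.3f)\n",
                nrow(x$contacts), x$call$label, x$call$best_score))
  }
  invisible(x)
}

#' All-vs-all subunit interaction screen
#'
#' Runs the complex pipeline for every unordered pair of subunits and
#' collects the best EVcomplex score and interaction label per pair
#' (insufficient alignments are labelled `"insufficient"`).
#'
#' @param subunits Named list; each element is a list with `aln`
#'   (`ev_alignment`) and `loci` (gene-location data.frame).
#' @param config An [pipeline_config()].
#' @return List with `table` (data.frame subunit_a, subunit_b,
#'   best_score, label) and `matrix` (best-score matrix).
#' @export
screen_subunits <- function(subunits, config = pipeline_config()) {
  nm <- names(subunits)
  stopifnot(length(nm) >= 2L, !is.null(nm))
  rows <- list()
  mat <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)[-length(nm)]) {
    for (j in seq(i + 1L, length(nm))) {
      pid <- paste(nm[i], nm[j], sep = ":")
      res <- suppressWarnings(
        complex_pipeline(subunits[[i]]$aln, subunits[[j]]$aln,
                         subunits[[i]]$loci, subunits[[j]]$loci,
                         config = config, pair_id = pid))
      if (res$status == "ok") {
        best <- res$call$best_score
        label <- res$call$label
      } else {
        best <- NA_real_
        label <- "insufficient"
      }
      mat[i, j] <- mat[j, i] <- best
      rows[[pid]] <- data.frame(subunit_a = nm[i], subunit_b = nm[j],
                                best_score = best, label = label)
    }
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       matrix = mat)
}
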