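#' Potts model with planted inter-protein couplings
#'
#' Builds a ground-truth complex model for benchmarking: zero fields and
#' zero couplings everywhere except a chosen set of residue pairs, each
#' given a random q x q interaction pattern scaled to a fixed Frobenius
#' norm (`strength`). Inter-protein pairs straddle the concatenation
#' boundary (`i <= L_a < j`), intra pairs lie within one block. The
#' construction is deterministic given the seed.
#'
#' @param L_a,L_b Lengths of the two protein blocks.
#' @param q Number of states (default 6; the production alphabet is 21,
#'   reduced state spaces keep simulation studies small).
#' @param n_inter Number of planted inter-protein coupled pairs.
#' @param n_intra Number of planted intra-protein pairs (split over both
#'   blocks).
#' @param strength Frobenius norm of each planted coupling block
#'   (default 3).
#' @param seed RNG seed.
#' @return An object of class `ev_planted`: `model` (`ev_potts`),
#'   `inter_pairs`/`intra_pairs` (data.frames with columns i, j),
#'   `boundary`, `strength`.
#' @export
planted_complex_model <- function(L_a, L_b, q = 6L, n_inter = 12L,
                                  n_intra = 0L, strength = 3,
                                  seed = 1L) {
  stopifnot(L_a >= 1L, L_b >= 1L, q >= 2L, strength > 0)
  L <- L_a + L_b
  if (n_inter > L_a * L_b) stop("more inter pairs requested than available")
  n_intra_max <- choose(L_a, 2) + choose(L_b, 2)
  if (n_intra > n_intra_max) stop("more intra pairs requested than available")
  with_seed(seed, {
    inter_all <- expand.grid(i = seq_len(L_a), j = L_a + seq_len(L_b))
    inter <- inter_all[sample.int(nrow(inter_all), n_inter), , drop = FALSE]
    intra_a <- t(utils::combn(seq_len(L_a), 2L))
    intra_b <- t(utils::combn(L_a + seq_len(L_b), 2L))
    intra_all <- rbind(intra_a, intra_b)
    intra <- intra_all[sample.int(nrow(intra_all), n_intra), , drop = FALSE]
    pairs <- rbind(as.matrix(inter), intra)
    J <- array(0, dim = c(L, L, q, q))
    for (k in seq_len(nrow(pairs))) {
      K <- matrix(stats::rnorm(q * q), q, q)
      K <- K * (strength / sqrt(sum(K^2)))
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      J[i, j, , ] <- K
      J[j, i, , ] <- t(K)
    }
    model <- potts_model(matrix(0, L, q), J)
    base::structure(
      list(model = model,
           inter_pairs = data.frame(i = inter$i, j = inter$j),
           intra_pairs = data.frame(i = intra[, 1L], j = intra[, 2L]),
           boundary = L_a, strength = strength, q = q),
      class = "ev_planted")
  })
}

#' Sample sequences from a Potts model by Gibbs sampling
#'
#' Draws `n` sequences with a single-site Gibbs sampler: one long chain
#' with random initialization, `burn_in` full sweeps discarded, then one
#' sequence recorded every `thin` sweeps. Reproducible given `seed`
#' (R's RNG drives the sampler). Sampled states are mapped to alignment
#' symbols through the first q letters of the standard alphabet (gap
#' first), so the result feeds directly into the preprocessing and
#' fitting pipeline.
#'
#' @param model An `ev_potts`.
#' @param n Number of sequences to draw.
#' @param seed RNG seed (NULL to use the current RNG state).
#' @param burn_in Discarded initial sweeps (default 1000).
#' @param thin Sweeps between recorded samples (default 10).
#' @param ids Optional sequence identifiers; defaults to
#'   `seq0001_sp0001` style tags giving each sample its own species.
#' @return An `ev_alignment` of n sampled sequences.
#' @export
sample_potts <- function(model, n, seed = NULL, burn_in = 1000L,
                         thin = 10L, ids = NULL) {
  stopifnot(n >= 1L, burn_in >= 0L, thin >= 1L)
  enc <- with_seed(seed, {
    gibbs_sample_potts_cpp(model$h, as.numeric(model$J), model$L,
                           model$q, as.integer(n), as.integer(burn_in),
                           as.integer(thin)) + 1L
  })
  alphabet <- aa_alphabet(model$q)
  ids <- ids %||% sprintf("seq%04d_sp%04d", seq_len(n), seq_len(n))
  new_alignment(decode_alignment(enc, alphabet), ids)
}

#' Synthetic genome layouts for pairing tests
#'
#' Generates gene-location tables for two protein families across
#' `n_species` species with controlled contig assignments and nucleotide
#' distances. Schemes:
#' \describe{
#'   \item{simple}{one homolog each per species, same contig, 500 nt
#'     apart.}
#'   \item{far}{one homolog each, same contig, 12000 nt apart (violates
#'     the 10k cap).}
#'   \item{cross_contig}{one homolog each on different contigs.}
#'   \item{tie}{one A homolog with two B paralogs equidistant from it
#'     (tie-break exercise).}
#'   \item{paralogs}{`paralog_counts` homologs per family scattered over
#'     two contigs with randomized distances, including some beyond the
#'     10k cap.}
#' }
#' Accessions follow the `fam<k>_sp<num>` convention so the default
#' species-tag rule recovers the species key.
#'
#' @param n_species Number of species.
#' @param paralog_counts Integer vector length 2: homolog counts per
#'   species for families A and B (used by the `paralogs` scheme).
#' @param contig_scheme One of the schemes above.
#' @param seed RNG seed.
#' @return List with gene-location data.frames `loci_a`, `loci_b`.
#' @export
synthetic_genome <- function(n_species, paralog_counts = c(1L, 1L),
                             contig_scheme = c("simple", "far",
                                               "cross_contig", "tie",
                                               "paralogs"),
                             seed = 1L) {
  stopifnot(n_species >= 1L, all(paralog_counts >= 1L))
  contig_scheme <- match.arg(contig_scheme)
  with_seed(seed, {
    la <- list(); lb <- list()
    for (s in seq_len(n_species)) {
      sp <- sprintf("sp%04d", s)
      mk <- function(fam, k, contig, start, len = 900L) {
        data.frame(accession = sprintf("%s%d_%s", fam, k, sp),
                   species = sp, contig_id = contig,
                   nt_start = as.integer(start),
                   nt_end = as.integer(start + len),
                   gene_index = NA_integer_,
                   stringsAsFactors = FALSE)
      }
      if (contig_scheme == "simple") {
        la[[s]] <- mk("a", 1L, "c1", 1000L)
        lb[[s]] <- mk("b", 1L, "c1", 2400L)
      } else if (contig_scheme == "far") {
        la[[s]] <- mk("a", 1L, "c1", 1000L)
        lb[[s]] <- mk("b", 1L, "c1", 1000L + 900L + 12000L)
      } else if (contig_scheme == "cross_contig") {
        la[[s]] <- mk("a", 1L, "c1", 1000L)
        lb[[s]] <- mk("b", 1L, "c2", 2400L)
      } else if (contig_scheme == "tie") {
        la[[s]] <- mk("a", 1L, "c1", 10000L)
        lb[[s]] <- rbind(mk("b", 1L, "c1", 10000L - 900L - 500L),
                         mk("b", 2L, "c1", 10000L + 900L + 500L))
      } else {
        pos_a <- sort(sample.int(40000L, paralog_counts[1L]))
        pos_b <- sort(sample.int(40000L, paralog_counts[2L]))
        contigs <- c("c1", "c2")
        la[[s]] <- do.call(rbind, lapply(seq_along(pos_a), function(k) {
          mk("a", k, sample(contigs, 1L), pos_a[k] * 2L)
        }))
        lb[[s]] <- do.call(rbind, lapply(seq_along(pos_b), function(k) {
          mk("b", k, sample(contigs, 1L), pos_b[k] * 2L)
        }))
      }
    }
    number_genes <- function(df) {
      df <- df[order(df$species, df$contig_id, df$nt_start), , drop = FALSE]
      df$gene_index <- stats::ave(
        df$nt_start, paste(df$species, df$contig_id),
        FUN = seq_along)
      df
    }
    all_loci <- number_genes(rbind(
      cbind(do.call(rbind, la), fam = "a"),
      cbind(do.call(rbind, lb), fam = "b")))
    list(loci_a = all_loci[all_loci$fam == "a",
                           setdiff(names(all_loci), "fam"), drop = FALSE],
         loci_b = all_loci[all_loci$fam == "b",
                           setdiff(names(all_loci), "fam"), drop = FALSE])
  })
}

#' Simulate a complete paired-alignment data set
#'
#' End-to-end fixture generator: samples `n_species` concatenated
#' sequences from a planted complex model, splits them into per-protein
#' alignments (one homolog per species), and lays the genes out with the
#' `simple` genome scheme so that pairing, concatenation, fitting and
#' scoring can run with no external inputs. When `dir` is given, writes
#' `aln_a.fasta`, `aln_b.fasta`, `loci_a.tsv`, `loci_b.tsv` and
#' `truth.json` (the planted pairs).
#'
#' @param n_species Number of species (= sequences).
#' @param truth An `ev_planted` model, or NULL to build one from the
#'   remaining arguments.
#' @param L_a,L_b,q,n_inter,n_intra,strength See
#'   [planted_complex_model()].
#' @param seed RNG seed.
#' @param dir Optional output directory.
#' @return List with `aln_a`, `aln_b`, `loci_a`, `loci_b`, `truth`, and
#'   (when written) `paths`.
#' @export
simulate_complex_dataset <- function(n_species, truth = NULL,
                                     L_a = 30L, L_b = 25L, q = 6L,
                                     n_inter = 12L, n_intra = 10L,
                                     strength = 3, seed = 1L,
                                     dir = NULL) {
  truth <- truth %||% planted_complex_model(L_a, L_b, q = q,
                                            n_inter = n_inter,
                                            n_intra = n_intra,
                                            strength = strength,
                                            seed = seed)
  species <- sprintf("sp%04d", seq_len(n_species))
  aln <- sample_potts(truth$model, n_species, seed = seed + 1L,
                      ids = paste0("ab_", species))
  genome <- synthetic_genome(n_species, contig_scheme = "simple",
                             seed = seed + 2L)
  aln_a <- new_alignment(
    aln$matrix[, seq_len(truth$boundary), drop = FALSE],
    ids = paste0("a1_", species))
  aln_b <- new_alignment(
    aln$matrix[, -seq_len(truth$boundary), drop = FALSE],
    ids = paste0("b1_", species))
  out <- list(aln_a = aln_a, aln_b = aln_b,
              loci_a = genome$loci_a, loci_b = genome$loci_b,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      aln_a = file.path(dir, "aln_a.fasta"),
      aln_b = file.path(dir, "aln_b.fasta"),
      loci_a = file.path(dir, "loci_a.tsv"),
      loci_b = file.path(dir, "loci_b.tsv"),
      truth = file.path(dir, "truth.json"))
    write_alignment(aln_a, paths$aln_a, "fasta")
    write_alignment(aln_b, paths$aln_b, "fasta")
    write_gene_loci(genome$loci_a, paths$loci_a)
    write_gene_loci(genome$loci_b, paths$loci_b)
    jsonlite::write_json(
      list(boundary = truth$boundary, q = truth$q,
           strength = truth$strength,
           inter_pairs = truth$inter_pairs,
           intra_pairs = truth$intra_pairs),
      paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
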