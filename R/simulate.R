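# Synthetic multi-subject paired-chain repertoires with ground truth.
#
# The generator emulates the statistical structure of an IgE-sorted
# single-cell antibody discovery experiment: clonal families seeded by a
# founder V(D)J recombination, members diversified by somatic
# hypermutation; a handful of public (convergent) families planted across
# subjects among many private ones; paired expression counts in which
# plasmablasts are PRDM1-high/MS4A1-low and memory cells the reverse;
# and labelled QC defects injected at configurable rates.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

.nonstop_codons <- local({
  all3 <- as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)),
                          .BASES, paste0))
  setdiff(all3, .STOP_CODONS)
})

.random_codons <- function(n) {
  paste(sample(.nonstop_codons, n, replace = TRUE), collapse = "")
}

# Per-site substitutions at `rate`; every flagged site is changed to a
# different base, chosen so the containing (frame-0) codon is not a stop.
# Realized mismatch count is therefore exactly Binomial(L, rate).
.mutate_nt <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hits <- which(runif(length(chars)) < rate)
  for (p in hits) {
    codon_start <- ((p - 1L) %/% 3L) * 3L + 1L
    for (b in sample(setdiff(.BASES, chars[p]))) {
      cand <- chars
      cand[p] <- b
      codon <- paste(cand[codon_start:(codon_start + 2L)], collapse = "")
      if (!codon %in% .STOP_CODONS) { chars <- cand; break }
    }
  }
  paste(chars, collapse = "")
}

# Per-codon CDR3 substitution model: with probability `rate` a codon gets
# one random non-stop single-base change. Length is always preserved so
# family members share their clone key by construction.
.mutate_cdr3 <- function(seq, rate) {
  n_codons <- nchar(seq) %/% 3L
  chars <- strsplit(seq, "")[[1]]
  for (ci in which(runif(n_codons) < rate)) {
    p <- (ci - 1L) * 3L + sample(3L, 1L)
    for (b in sample(setdiff(.BASES, chars[p]))) {
      cand <- chars
      cand[p] <- b
      codon <- paste(cand[((ci - 1L) * 3L + 1L):(ci * 3L)], collapse = "")
      if (!codon %in% .STOP_CODONS) { chars <- cand; break }
    }
  }
  paste(chars, collapse = "")
}

# Bundled toy germline segments: 10 V (300 nt, Cys codon last) and 4 J
# per locus, generated once from a fixed internal seed. A stand-in for a
# real germline reference, synthetic by design: the pipeline never
# depends on true human gene sequences.
.germline_cache <- new.env(parent = emptyenv())

#' Toy germline segment set
#'
#' Deterministic synthetic V (300 nt) and J (33 nt) segments, ten V and
#' four J per locus, used by [simulate_repertoire()].
#'
#' @return Nested list: `$IGH$V`, `$IGH$J`, ... named nucleotide vectors.
#' @export
toy_germline <- function() {
  if (!is.null(.germline_cache$set)) return(.germline_cache$set)
  set <- with_seed(8675309, {
    out <- list()
    for (locus in c("IGH", "IGK", "IGL")) {
      v <- vapply(1:10, function(i) {
        paste0(.random_codons(99L), "TGT")  # conserved 3' cysteine
      }, character(1))
      names(v) <- sprintf("%sV%d-1*01", locus, 1:10)
      anchor <- if (locus == "IGH") "TGG" else "TTT"
      j <- vapply(1:4, function(i) paste0(anchor, .random_codons(10L)),
                  character(1))
      names(j) <- sprintf("%sJ%d*01", locus, 1:4)
      out[[locus]] <- list(V = v, J = j)
    }
    out
  })
  .germline_cache$set <- set
  set
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is verified under:
#' 8 subjects of 150 cells, 3 public and 40 private clonal families,
#' 2% per-site V-region hypermutation over 300 nt V segments, 5%
#' per-codon CDR3 diversification, labelled QC defects at a few percent
#' each, an IgE-dominated isotype mix, a plasmablast-biased state mix
#' with 8-fold PRDM1/MS4A1 asymmetry.
#'
#' @param n_subjects,cells_per_subject Cohort shape (total cells is the
#'   product).
#' @param n_public_families Convergent families planted across >= 2
#'   subjects.
#' @param n_private_families Single-subject families.
#' @param shm_rate_per_site Per-nucleotide V-region mutation rate.
#' @param cdr3_intra_family_mutation_rate Per-codon CDR3 substitution
#'   rate within a family (capped at 0.1 so expected intra-family
#'   identity stays >= 0.8).
#' @param defect_rates Named fractions for planted defect classes
#'   (`stop_codon`, `ambiguous_nt`, `short_v`, `low_genes`, `multiplet`,
#'   `ambiguous_c_call`); at most one defect is planted per cell.
#' @param isotype_mix Named fractions summing to 1.
#' @param plasmablast_fraction Fraction of cells in the plasmablast state.
#' @param marker_fold_change PRDM1/MS4A1 mean asymmetry between states.
#' @param nb_dispersion Negative-binomial size parameter for counts.
#' @param n_genes Genes in the expression matrix (includes PRDM1, MS4A1
#'   and a 100-gene state-dependent program).
#' @param seed RNG seed; every random draw in the simulator flows from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_subjects = 8L, cells_per_subject = 150L,
                              n_public_families = 3L,
                              n_private_families = 40L,
                              shm_rate_per_site = 0.02,
                              cdr3_intra_family_mutation_rate = 0.05,
                              defect_rates = c(stop_codon = 0.05,
                                               ambiguous_nt = 0.05,
                                               short_v = 0.05,
                                               low_genes = 0.05,
                                               multiplet = 0.03,
                                               ambiguous_c_call = 0.02),
                              isotype_mix = c(IgE = 0.85, IgG = 0.10,
                                              IgM = 0.05),
                              plasmablast_fraction = 0.6,
                              marker_fold_change = 8,
                              nb_dispersion = 4,
                              n_genes = 1500L,
                              seed = 42L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              cells_per_subject = as.integer(cells_per_subject),
              n_public_families = as.integer(n_public_families),
              n_private_families = as.integer(n_private_families),
              shm_rate_per_site = shm_rate_per_site,
              cdr3_intra_family_mutation_rate = cdr3_intra_family_mutation_rate,
              defect_rates = defect_rates,
              isotype_mix = isotype_mix,
              plasmablast_fraction = plasmablast_fraction,
              marker_fold_change = marker_fold_change,
              nb_dispersion = nb_dispersion,
              n_genes = as.integer(n_genes),
              seed = as.integer(seed))
  fr <- c(cfg$shm_rate_per_site, cfg$cdr3_intra_family_mutation_rate,
          cfg$defect_rates, cfg$isotype_mix, cfg$plasmablast_fraction)
  if (any(fr < 0 | fr > 1)) stop("all rates and fractions must lie in [0, 1]")
  if (abs(sum(cfg$isotype_mix) - 1) > 1e-9) stop("isotype_mix must sum to 1")
  if (sum(cfg$defect_rates) > 1) stop("defect rates must sum to at most 1")
  if (cfg$cdr3_intra_family_mutation_rate > 0.1) {
    stop("cdr3_intra_family_mutation_rate above 0.1 would push expected ",
         "intra-family identity below 0.8")
  }
  if (cfg$n_public_families > 0 && cfg$n_subjects < 2) {
    stop("public families require at least 2 subjects")
  }
  total_cells <- cfg$n_subjects * cfg$cells_per_subject
  n_fam <- cfg$n_public_families + cfg$n_private_families
  if (n_fam > total_cells) stop("more families than cells")
  structure(cfg, class = "simulation_config")
}

.c_call_for <- c(IgE = "IGHE", IgG = "IGHG1", IgA = "IGHA1",
                 IgM = "IGHM", IgD = "IGHD")

#' Simulate a paired-chain repertoire with matched expression counts
#'
#' Emits an AIRR-style rearrangement table (one heavy and one light row
#' per cell, plus extra heavy rows for planted multiplets), a gene-by-cell
#' count matrix, and the full ground truth (per-cell family, state,
#' isotype, planted defect; per-family public flag and founder CDR3).
#' The whole run is reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List: `rearrangements` (canonical data frame), `expression`
#'   (integer matrix), `truth` (list with `cells` and `families` data
#'   frames), `config`.
#' @export
simulate_repertoire <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, .simulate_repertoire_impl(config))
}

.simulate_repertoire_impl <- function(cfg) {
  germ <- toy_germline()
  total_cells <- cfg$n_subjects * cfg$cells_per_subject
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  n_fam <- cfg$n_public_families + cfg$n_private_families

  # family definitions: founders and subject assignments
  fams <- vector("list", n_fam)
  public_sizes <- if (cfg$n_public_families > 0) {
    sample(10:16, cfg$n_public_families, replace = TRUE)
  } else integer(0)
  n_left <- total_cells - sum(public_sizes)
  w <- stats::rexp(cfg$n_private_families)
  private_sizes <- pmax(1L, floor(n_left * w / sum(w)))
  while (sum(private_sizes) > n_left) {
    i <- which.max(private_sizes); private_sizes[i] <- private_sizes[i] - 1L
  }
  while (sum(private_sizes) < n_left) {
    i <- sample(cfg$n_private_families, 1L)
    private_sizes[i] <- private_sizes[i] + 1L
  }
  sizes <- c(public_sizes, private_sizes)
  for (f in seq_len(n_fam)) {
    public <- f <= cfg$n_public_families
    light_locus <- sample(c("IGK", "IGL"), 1L)
    member_subjects <- if (public) {
      ns <- sample(2:min(5L, cfg$n_subjects), 1L)
      chosen <- sample(subjects, ns)
      # every chosen subject contributes at least one member
      s <- c(chosen, sample(chosen, sizes[f] - ns, replace = TRUE))
      sample(s)
    } else {
      rep(sample(subjects, 1L), sizes[f])
    }
    fams[[f]] <- list(
      family_id = sprintf("F%03d", f), public = public, size = sizes[f],
      subjects = member_subjects,
      heavy_v = sample(names(germ$IGH$V), 1L),
      heavy_j = sample(names(germ$IGH$J), 1L),
      heavy_cdr3 = .random_codons(sample(10:16, 1L)),
      light_locus = light_locus,
      light_v = sample(names(germ[[light_locus]]$V), 1L),
      light_j = sample(names(germ[[light_locus]]$J), 1L),
      light_cdr3 = .random_codons(sample(8:10, 1L)))
  }

  defect_classes <- names(cfg$defect_rates)
  defect_probs <- c(cfg$defect_rates, none = 1 - sum(cfg$defect_rates))

  rec_rows <- list()
  truth_rows <- list()
  cell_counter <- 0L
  for (f in seq_len(n_fam)) {
    fam <- fams[[f]]
    for (k in seq_len(fam$size)) {
      cell_counter <- cell_counter + 1L
      cell_id <- sprintf("cell%05d", cell_counter)
      subj <- fam$subjects[k]
      sample_id <- paste0(subj, "-", sample(3L, 1L))
      isotype <- sample(names(cfg$isotype_mix), 1L, prob = cfg$isotype_mix)
      state <- if (runif(1) < cfg$plasmablast_fraction) "plasmablast"
               else "naive_memory"
      defect <- sample(names(defect_probs), 1L, prob = defect_probs)

      h_germ <- germ$IGH$V[[fam$heavy_v]]
      h_v <- .mutate_nt(h_germ, cfg$shm_rate_per_site)
      h_cdr3 <- .mutate_cdr3(fam$heavy_cdr3,
                             cfg$cdr3_intra_family_mutation_rate)
      h_len <- 300L
      h_c_call <- .c_call_for[[isotype]]

      l_germ <- germ[[fam$light_locus]]$V[[fam$light_v]]
      l_v <- .mutate_nt(l_germ, cfg$shm_rate_per_site)
      l_cdr3 <- .mutate_cdr3(fam$light_cdr3,
                             cfg$cdr3_intra_family_mutation_rate)
      l_c_call <- if (fam$light_locus == "IGK") "IGKC" else "IGLC1"

      if (defect == "stop_codon") {
        ci <- sample(2:99, 1L)
        substr(h_v, (ci - 1L) * 3L + 1L, ci * 3L) <- "TAA"
      } else if (defect == "ambiguous_nt") {
        pos <- sample(300L, 1L)
        substr(h_v, pos, pos) <- "N"
      } else if (defect == "short_v") {
        h_v <- substr(h_v, 103L, 300L)
        h_germ <- substr(h_germ, 103L, 300L)
        h_len <- 198L
      } else if (defect == "ambiguous_c_call") {
        h_c_call <- "IGHE,IGHG1"
      }

      mk_row <- function(locus, v_call, j_call, vseq, cdr3, vlen, vgerm,
                         jseq, c_call) {
        list(
          cell_id = cell_id, subject_id = subj, sample_id = sample_id,
          locus = locus, v_call = v_call, j_call = j_call,
          sequence = paste0(vseq, cdr3, jseq), sequence_aa = "",
          junction_aa = "", cdr3_aa = "", cdr3_nt = cdr3,
          v_sequence_length = vlen, v_germline = vgerm,
          productive = TRUE, c_call = c_call, frame_offset = 0L)
      }
      heavy_row <- mk_row("IGH", fam$heavy_v, fam$heavy_j, h_v, h_cdr3,
                          h_len, h_germ, germ$IGH$J[[fam$heavy_j]], h_c_call)
      rec_rows[[length(rec_rows) + 1L]] <- heavy_row
      rec_rows[[length(rec_rows) + 1L]] <-
        mk_row(fam$light_locus, fam$light_v, fam$light_j, l_v, l_cdr3,
               300L, l_germ, germ[[fam$light_locus]]$J[[fam$light_j]],
               l_c_call)
      if (defect == "multiplet") {
        extra <- heavy_row
        extra$v_call <- sample(names(germ$IGH$V), 1L)
        rec_rows[[length(rec_rows) + 1L]] <- extra
      }

      truth_rows[[cell_counter]] <- list(
        cell_id = cell_id, subject_id = subj, sample_id = sample_id,
        family_id = fam$family_id, public = fam$public, state = state,
        isotype = isotype, defect = defect)
    }
  }
  rearrangements <- as.data.frame(data.table::rbindlist(rec_rows))
  rearrangements$cdr3_aa <- translate_dna(rearrangements$cdr3_nt)
  truth_cells <- as.data.frame(data.table::rbindlist(truth_rows))

  expression <- .simulate_expression(cfg, truth_cells)

  truth_families <- do.call(rbind, lapply(fams, function(fam) {
    data.frame(family_id = fam$family_id, public = fam$public,
               n_members = fam$size,
               founder_cdr3_aa = translate_dna(fam$heavy_cdr3),
               subjects = paste(sort(unique(fam$subjects)), collapse = ","),
               row.names = NULL)
  }))

  list(rearrangements = rearrangements, expression = expression,
       truth = list(cells = truth_cells, families = truth_families),
       config = cfg)
}

# Counts: lognormal per-gene baseline means, NB noise; PRDM1/MS4A1 and a
# 100-gene state program carry the plasmablast/memory signal (plasmablasts
# differ from memory cells in a broad transcriptional program, not just
# the two markers — this is what lets PCA recover the partition).
.simulate_expression <- function(cfg, truth_cells) {
  n_cells <- nrow(truth_cells)
  genes <- c("PRDM1", "MS4A1", sprintf("GENE%04d", seq_len(cfg$n_genes - 2L)))
  mu_base <- stats::rlnorm(cfg$n_genes, meanlog = 1.0, sdlog = 1)
  m <- matrix(0L, cfg$n_genes, n_cells, dimnames = list(genes,
                                                        truth_cells$cell_id))
  is_pb <- truth_cells$state == "plasmablast"
  hi <- 120; lo <- 120 / cfg$marker_fold_change
  mu <- matrix(rep(mu_base, n_cells), cfg$n_genes, n_cells)
  mu[1, ] <- ifelse(is_pb, hi, lo)     # PRDM1
  mu[2, ] <- ifelse(is_pb, lo, hi)     # MS4A1
  # state program: genes 3..52 up in plasmablasts, 53..102 up in memory
  prog_up <- 3:52; prog_dn <- 53:102
  mu[prog_up, is_pb] <- mu[prog_up, is_pb] * 4
  mu[prog_dn, !is_pb] <- mu[prog_dn, !is_pb] * 4
  m[] <- rnbinom(length(mu), size = cfg$nb_dispersion, mu = as.vector(mu))
  # planted low-gene-count defect: keep 300 random genes, zero the rest
  for (j in which(truth_cells$defect == "low_genes")) {
    keep <- sample(cfg$n_genes, 300L)
    m[-keep, j] <- 0L
  }
  storage.mode(m) <- "integer"
  m
}

#' Simulate a linear peptide-array signal over a tiled protein
#'
#' Tiles the protein, finds planted motif copies, and assigns a high mean
#' signal to every tile containing at least one full copy (baseline
#' elsewhere) plus Gaussian noise.
#'
#' @param sequence Protein sequence carrying the planted motif.
#' @param motif Exact motif (default `"DPYSPS"`).
#' @param k,offset Tiling parameters (defaults 15 and 1).
#' @param signal_high,baseline Mean signals for motif-bearing and other
#'   tiles (defaults 10 and 0).
#' @param noise_sd Gaussian noise standard deviation (default 0.5).
#' @param seed Optional seed for the noise draw.
#' @return List: `tiles`, `signals`, `tile_has_motif` (logical ground
#'   truth per tile), `motif_hits` (planted copy coordinates).
#' @export
simulate_peptide_array <- function(sequence, motif = "DPYSPS", k = 15L,
                                   offset = 1L, signal_high = 10,
                                   baseline = 0, noise_sd = 0.5,
                                   seed = NULL) {
  tiles <- tile_protein(sequence, k = k, offset = offset)
  hits <- scan_motif(sequence, motif)
  has_motif <- vapply(seq_len(nrow(tiles)), function(i) {
    any(hits$start >= tiles$start[i] &
          hits$end <= tiles$start[i] + tiles$length[i])
  }, logical(1))
  mean_sig <- ifelse(has_motif, signal_high, baseline)
  noise <- if (noise_sd > 0) {
    if (is.null(seed)) rnorm(nrow(tiles), 0, noise_sd)
    else with_seed(seed, rnorm(nrow(tiles), 0, noise_sd))
  } else rep(0, nrow(tiles))
  list(tiles = tiles, signals = mean_sig + noise,
       tile_has_motif = has_motif, motif_hits = hits)
}
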