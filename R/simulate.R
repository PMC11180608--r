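# Seeded synthetic-homolog generator: families evolved from random
# ancestors by per-site substitution and geometric indels, with the implied
# ground-truth alignment and a planted TM-like label that decays with
# divergence. A stand-in for structure-derived training data so every
# module is testable offline; it does not model real substitution
# preferences (see the methods vignette for what it does and does not
# emulate).

#' Generator configuration for the synthetic pair corpus
#'
#' @param seed master seed; corpora are bit-identical under identical
#'   (config, seed).
#' @param n_families number of independent families.
#' @param members_per_family sequences evolved from each family ancestor.
#' @param length_range ancestor length range (uniform integer).
#' @param divergence_range per-member divergence range (uniform); a
#'   member's divergence d drives both mutation processes below.
#' @param sub_rate per-site substitution probability per unit divergence
#'   (replacement drawn uniformly from the 20 letters, so a small fraction
#'   is silent).
#' @param indel_rate per-site indel probability per unit divergence; indel
#'   lengths are 1 + Geometric(indel_geom_p) (mean 2 at the default 0.5).
#' @param indel_geom_p geometric parameter of the indel length.
#' @param lambda label decay: a related pair with member divergences d1, d2
#'   gets label `exp(-lambda * (d1 + d2)) + noise`.
#' @param noise_sd Gaussian label noise (default 0.02); labels are clamped
#'   to `[0, 1]`.
#' @param unrelated_frac cross-family pairs added as a fraction of the
#'   related pairs, labelled Uniform(0, 0.2) (mean 0.1, below the 0.2
#'   unrelated-pair TM-score convention).
#' @return a list of class `ea_generator_config`.
#' @export
generatorConfig <- function(seed = 1L, n_families = 25L,
                            members_per_family = 4L,
                            length_range = c(40L, 80L),
                            divergence_range = c(0.02, 0.5),
                            sub_rate = 1.0, indel_rate = 0.1,
                            indel_geom_p = 0.5, lambda = 2.0,
                            noise_sd = 0.02, unrelated_frac = 0.2) {
  stopifnot(n_families >= 1, members_per_family >= 2,
            length_range[1] >= 5, length_range[2] >= length_range[1],
            all(divergence_range >= 0), sub_rate >= 0, sub_rate <= 1,
            indel_rate >= 0, indel_rate < 1, indel_geom_p > 0,
            indel_geom_p <= 1, lambda > 0, noise_sd >= 0,
            unrelated_frac >= 0)
  structure(as.list(environment()), class = "ea_generator_config")
}

# mutate ancestor characters at divergence d; returns the mutated character
# vector and the monotone map ancestor position -> descendant position
# (NA where deleted)
.evolve_member <- function(anc, d, cfg) {
  n <- length(anc)
  chars <- anc
  sub_mask <- stats::runif(n) < cfg$sub_rate * d
  if (any(sub_mask))
    chars[sub_mask] <- sample(.AA_ALPHABET, sum(sub_mask), replace = TRUE)
  # walk the sequence emitting indels; map[k] = descendant index of anc k
  out <- character(0)
  map <- rep(NA_integer_, n)
  p_indel <- cfg$indel_rate * d
  k <- 1L
  while (k <= n) {
    if (stats::runif(1) < p_indel) {
      L <- 1L + stats::rgeom(1, cfg$indel_geom_p)
      if (stats::runif(1) < 0.5) {
        # deletion of L ancestor positions
        k <- k + L
        next
      } else {
        # insertion of L random residues before anc position k
        out <- c(out, sample(.AA_ALPHABET, L, replace = TRUE))
      }
    }
    out <- c(out, chars[k])
    map[k] <- length(out)
    k <- k + 1L
  }
  if (!length(out)) { # pathological total deletion: keep one residue
    out <- chars[n]
    map[n] <- 1L
  }
  list(seq = paste(out, collapse = ""), map = map)
}

# state string between two descendants of the same ancestor, composed from
# their ancestor-position maps
.compose_states <- function(map_a, map_b, len_a, len_b) {
  keep <- which(!is.na(map_a) & !is.na(map_b))
  ea <- map_a[keep]; eb <- map_b[keep]
  states <- character(0)
  ia <- 0L; ib <- 0L
  emit_gap <- function(states, ia, ib, ta, tb) {
    if (ta > ia) states <- c(states, rep("X", ta - ia))
    if (tb > ib) states <- c(states, rep("Y", tb - ib))
    states
  }
  for (m in seq_along(ea)) {
    states <- emit_gap(states, ia, ib, ea[m] - 1L, eb[m] - 1L)
    states <- c(states, "M")
    ia <- ea[m]; ib <- eb[m]
  }
  states <- emit_gap(states, ia, ib, len_a, len_b)
  paste(states, collapse = "")
}

#' Generate a synthetic corpus of homologous pairs
#'
#' Families are evolved from random ancestors; within-family pairs carry
#' the ground-truth alignment implied by the mutation/indel history
#' (substitutions keep the match edge, indels create X/Y states) and a
#' planted label `exp(-lambda * divergence) + noise` standing in for a
#' TM-score. Cross-family pairs are labelled from a low-similarity
#' distribution and carry no alignment.
#'
#' @param config a [generatorConfig()].
#' @return list with `sequences` (named character), `pairs` (data.frame
#'   `id_a`, `id_b`, `label`, `divergence`, `related`), `alignments`
#'   (data.frame `id_a`, `id_b`, `states`, `tm` for related pairs) and
#'   `annotations` (data.frame `id`, `label` = family id).
#' @export
generatePairCorpus <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "ea_generator_config"))
  nn_seed_rng(config$seed)
  seqs <- character(0)
  members <- list() # per family: list of list(id, d, map, len)
  for (f in seq_len(config$n_families)) {
    alen <- sample(config$length_range[1]:config$length_range[2], 1)
    anc <- sample(.AA_ALPHABET, alen, replace = TRUE)
    fam <- vector("list", config$members_per_family)
    for (m in seq_len(config$members_per_family)) {
      d <- stats::runif(1, config$divergence_range[1],
                        config$divergence_range[2])
      ev <- .evolve_member(anc, d, config)
      id <- sprintf("F%03d_M%02d", f, m)
      seqs[id] <- ev$seq
      fam[[m]] <- list(id = id, d = d, map = ev$map, len = nchar(ev$seq))
    }
    members[[f]] <- fam
  }
  pairs <- NULL; aligns <- NULL
  for (f in seq_len(config$n_families)) {
    fam <- members[[f]]
    for (a in seq_len(length(fam) - 1)) {
      for (b in (a + 1):length(fam)) {
        div <- fam[[a]]$d + fam[[b]]$d
        label <- exp(-config$lambda * div) +
          stats::rnorm(1, 0, config$noise_sd)
        label <- min(1, max(0, label))
        states <- .compose_states(fam[[a]]$map, fam[[b]]$map,
                                  fam[[a]]$len, fam[[b]]$len)
        pairs <- rbind(pairs, data.frame(
          id_a = fam[[a]]$id, id_b = fam[[b]]$id, label = label,
          divergence = div, related = TRUE))
        aligns <- rbind(aligns, data.frame(
          id_a = fam[[a]]$id, id_b = fam[[b]]$id, states = states,
          tm = label))
      }
    }
  }
  n_unrel <- round(config$unrelated_frac * nrow(pairs))
  if (n_unrel > 0 && config$n_families >= 2) {
    for (u in seq_len(n_unrel)) {
      fs <- sample(config$n_families, 2)
      ma <- sample(members[[fs[1]]], 1)[[1]]
      mb <- sample(members[[fs[2]]], 1)[[1]]
      pairs <- rbind(pairs, data.frame(
        id_a = ma$id, id_b = mb$id, label = stats::runif(1, 0, 0.2),
        divergence = NA_real_, related = FALSE))
    }
  }
  annotations <- data.frame(
    id = names(seqs),
    label = sub("_M[0-9]+$", "", names(seqs)))
  rownames(pairs) <- NULL
  list(sequences = seqs, pairs = pairs, alignments = aligns,
       annotations = annotations)
}

#' Generate labelled Gaussian-blob vectors
#'
#' Fixture generator for the embedding metrics and the vector index:
#' `n_classes` isotropic Gaussian blobs in `d` dimensions whose centres are
#' drawn with standard deviation `separation` (0 = identical blobs =
#' chance-level structure).
#'
#' @param n_classes number of blobs (labels).
#' @param per_class points per blob.
#' @param d dimension.
#' @param separation centre standard deviation relative to unit
#'   within-blob noise.
#' @param seed RNG seed.
#' @return list with `vectors` (matrix) and `labels`.
#' @export
generateLabeledVectors <- function(n_classes = 5L, per_class = 40L, d = 16L,
                                   separation = 3, seed = 1L) {
  nn_seed_rng(seed)
  centers <- matrix(stats::rnorm(n_classes * d, sd = separation),
                    n_classes, d)
  vecs <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    sweep(matrix(stats::rnorm(per_class * d), per_class, d), 2,
          centers[k, ], `+`)
  }))
  list(vectors = vecs, labels = rep(seq_len(n_classes), each = per_class))
}

#' Write a synthetic corpus to a directory
#'
#' Emits `sequences.fasta`, `pairs.tsv`, `alignments.tsv` and
#' `annotations.tsv`.
#'
#' @param corpus result of [generatePairCorpus()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFastaSequences(corpus$sequences, file.path(dir, "sequences.fasta"))
  utils::write.table(corpus$pairs, file.path(dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$alignments, file.path(dir, "alignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(corpus$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
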