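# Synthetic-data generators. Every generator is a pure function of its
# arguments: randomness is drawn under a local seed and the caller's RNG
# state is untouched.

#' Simulation configuration for synthetic protein families
#'
#' Bundles the parameters controlling the synthetic FUK/GFPP/FKP family
#' generator, the HMM hit-table emulator, and the fusion-history tree
#' generator. Defaults are sized like real members of the family: a
#' C-terminal kinase (FUK) domain of 400 residues, an N-terminal
#' pyrophosphorylase (GFPP) domain of 480 residues and a 20-residue
#' linker, so full-length fused proteins are 900 residues and pass the
#' standard length filters (333/406/739, maximum 1745).
#'
#' @param seed integer seed for all randomness.
#' @param n_fuk,n_gfpp,n_fkp number of sequences per family.
#' @param domain_len_fuk,domain_len_gfpp domain lengths in residues.
#' @param linker_len linker length (residues) between the GFPP and FUK
#'   moieties of fused proteins.
#' @param substitution_rate expected substitutions per site on the branch
#'   from the family ancestor to each extant sequence; must be in `[0, 1)`.
#' @param score_noise_sd Gaussian noise (bit-score units) added to hit
#'   scores by [gen_hit_table()].
#' @param tree_n_tips number of tips of the fusion-history tree.
#' @param fusion_clade_size number of tips in the fused clade.
#' @param loss_count number of fusion losses within the fused clade.
#' @return a list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, n_fkp = 3)
#' @export
sim_config <- function(seed = 1L,
                       n_fuk = 4L, n_gfpp = 4L, n_fkp = 4L,
                       domain_len_fuk = 400L, domain_len_gfpp = 480L,
                       linker_len = 20L,
                       substitution_rate = 0.05,
                       score_noise_sd = 2,
                       tree_n_tips = 16L, fusion_clade_size = 5L,
                       loss_count = 0L) {
  stopifnot(
    is_count(n_fuk), is_count(n_gfpp), is_count(n_fkp),
    is_count(domain_len_fuk), is_count(domain_len_gfpp),
    is_count(linker_len),
    is_number(substitution_rate), substitution_rate >= 0,
    substitution_rate < 1,
    is_number(score_noise_sd), score_noise_sd >= 0,
    is_count(tree_n_tips), is_count(fusion_clade_size),
    is_count(loss_count)
  )
  if (fusion_clade_size > tree_n_tips)
    stop("fusion_clade_size must not exceed tree_n_tips")
  structure(list(
    seed = as.integer(seed),
    n_fuk = as.integer(n_fuk), n_gfpp = as.integer(n_gfpp),
    n_fkp = as.integer(n_fkp),
    domain_len_fuk = as.integer(domain_len_fuk),
    domain_len_gfpp = as.integer(domain_len_gfpp),
    linker_len = as.integer(linker_len),
    substitution_rate = substitution_rate,
    score_noise_sd = score_noise_sd,
    tree_n_tips = as.integer(tree_n_tips),
    fusion_clade_size = as.integer(fusion_clade_size),
    loss_count = as.integer(loss_count)
  ), class = "sim_config")
}

random_protein <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                    collapse = "")

# uniform point substitutions, no indels: each site mutates with
# probability `rate` to one of the 19 other residues, uniformly
mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate synthetic FUK, GFPP and fused FKP protein families
#'
#' Draws a uniform-random ancestor per monofunctional family, derives
#' family members as independently point-mutated copies, and builds fused
#' FKP proteins as `GFPP ancestor + linker + FUK ancestor` concatenations
#' (mirroring the N-terminal-GFPP / C-terminal-FUK architecture of real
#' FKPs), also point-mutated. No indels are introduced, so sequence
#' lengths are deterministic functions of the configuration.
#'
#' @param config a [sim_config()].
#' @return a list with elements `proteins` (data.frame: `id`, `sequence`,
#'   `length`) and `truth` (data.frame: `id`, `family` in
#'   FUK/GFPP/FKP).
#' @examples
#' fam <- gen_domain_families(sim_config(seed = 1))
#' table(fam$truth$family)
#' @export
gen_domain_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_fuk + config$n_fkp > 0 && config$domain_len_fuk == 0)
    stop("domain_len_fuk must be positive")
  if (config$n_gfpp + config$n_fkp > 0 && config$domain_len_gfpp == 0)
    stop("domain_len_gfpp must be positive")
  with_seed(config$seed, {
    anc_fuk  <- random_protein(config$domain_len_fuk)
    anc_gfpp <- random_protein(config$domain_len_gfpp)
    linker   <- random_protein(config$linker_len)
    anc_fkp  <- paste0(anc_gfpp, linker, anc_fuk)
    ids <- character(0); seqs <- character(0); fams <- character(0)
    if (config$n_fuk > 0) {
      ids  <- c(ids, sprintf("FUK%02d", seq_len(config$n_fuk)))
      seqs <- c(seqs, vapply(seq_len(config$n_fuk), function(i)
        mutate_protein(anc_fuk, config$substitution_rate), ""))
      fams <- c(fams, rep("FUK", config$n_fuk))
    }
    if (config$n_gfpp > 0) {
      ids  <- c(ids, sprintf("GFPP%02d", seq_len(config$n_gfpp)))
      seqs <- c(seqs, vapply(seq_len(config$n_gfpp), function(i)
        mutate_protein(anc_gfpp, config$substitution_rate), ""))
      fams <- c(fams, rep("GFPP", config$n_gfpp))
    }
    if (config$n_fkp > 0) {
      ids  <- c(ids, sprintf("FKP%02d", seq_len(config$n_fkp)))
      seqs <- c(seqs, vapply(seq_len(config$n_fkp), function(i)
        mutate_protein(anc_fkp, config$substitution_rate), ""))
      fams <- c(fams, rep("FKP", config$n_fkp))
    }
    list(
      proteins = data.frame(id = ids, sequence = seqs,
                            length = nchar(seqs),
                            stringsAsFactors = FALSE),
      truth = data.frame(id = ids, family = fams, stringsAsFactors = FALSE)
    )
  })
}

# noiseless mean hit scores per true family; chosen so that the standard
# membership rules recover truth exactly at zero noise: monofunctional
# families rank their own model first and decoys second, fused proteins
# rank all three target models in their top three with PRK13412 highest
HIT_SCORE_MEANS <- list(
  FUK  = c(COG2605 = 95, PF07959 = 5,  PRK13412 = 8),
  GFPP = c(COG2605 = 5,  PF07959 = 95, PRK13412 = 8),
  FKP  = c(COG2605 = 95, PF07959 = 90, PRK13412 = 110)
)
DECOY_MODELS <- sprintf("DECOY%d", 1:5)
DECOY_MEAN <- 20

#' Generate a ranked profile-HMM hit table for labelled proteins
#'
#' Emulates an hmmscan-style tabular output: every protein receives
#' scored hits to the three target models (COG2605 for the kinase domain,
#' PF07959 for the pyrophosphorylase domain, PRK13412 for full-length
#' fused proteins) plus five decoy models, with Gaussian score noise.
#' Noiseless mean scores reflect the true architecture, so ranking the
#' models recovers the truth exactly at `score_noise_sd = 0`.
#'
#' @param proteins data.frame with an `id` column (as from
#'   [gen_domain_families()]).
#' @param truth data.frame with `id` and `family` columns covering every
#'   protein.
#' @param score_noise_sd Gaussian score noise standard deviation.
#' @param seed integer seed.
#' @return a data.frame (`query_id`, `model_id`, `score`) suitable for
#'   [classify_architecture()] and TSV serialization; scores are
#'   truncated at zero.
#' @examples
#' fam <- gen_domain_families(sim_config(seed = 1))
#' hits <- gen_hit_table(fam$proteins, fam$truth, score_noise_sd = 0)
#' @export
gen_hit_table <- function(proteins, truth, score_noise_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(proteins), "id" %in% names(proteins),
            is.data.frame(truth), all(c("id", "family") %in% names(truth)),
            is_number(score_noise_sd), score_noise_sd >= 0)
  fam <- truth$family[match(proteins$id, truth$id)]
  if (anyNA(fam)) stop("every protein must carry a truth label")
  if (!all(fam %in% names(HIT_SCORE_MEANS)))
    stop("unknown family label(s): ",
         paste(setdiff(fam, names(HIT_SCORE_MEANS)), collapse = ", "))
  models <- c(names(HIT_SCORE_MEANS$FUK), DECOY_MODELS)
  with_seed(seed, {
    rows <- lapply(seq_along(proteins$id), function(i) {
      means <- c(HIT_SCORE_MEANS[[fam[i]]],
                 stats::setNames(rep(DECOY_MEAN, length(DECOY_MODELS)),
                                 DECOY_MODELS))
      data.frame(query_id = proteins$id[i],
                 model_id = models,
                 score = pmax(0, means[models] +
                                stats::rnorm(length(models),
                                             sd = score_noise_sd)),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a fusion-history tree with a single gain and optional losses
#'
#' Generates a random rooted bifurcating tree with branch lengths in
#' which exactly one internal (or terminal, if the fused clade is a
#' single tip) branch carries the 0 to 1 gain of the fused state, and
#' `loss_count` terminal branches inside the gained clade carry 1 to 0
#' losses. The fused clade is built by grafting a random subtree of the
#' requested size, so a clade of exactly `fusion_clade_size` tips always
#' exists. Tips descending from the gain and not lost are in state 1.
#'
#' @param n_tips total number of tips (at least 2).
#' @param fusion_clade_size number of tips in the gained clade (at
#'   least 1).
#' @param loss_count number of losses; must be strictly smaller than
#'   `fusion_clade_size` so the gain remains observable.
#' @param seed integer seed.
#' @return a list with elements `tree` (rooted `ape::phylo`), `states`
#'   (named 0/1 integer vector over tips), `gain_node` (node number whose
#'   subtending branch carries the gain; the root node if the whole tree
#'   is fused) and `loss_tips` (tip labels whose terminal branches carry
#'   losses).
#' @examples
#' sim <- gen_fusion_tree(8, fusion_clade_size = 3, loss_count = 1, seed = 1)
#' sum(sim$states)  # 2 fused tips remain
#' @export
gen_fusion_tree <- function(n_tips, fusion_clade_size, loss_count = 0L,
                            seed = 1L) {
  stopifnot(is_count(n_tips), n_tips >= 2,
            is_count(fusion_clade_size, positive = TRUE),
            is_count(loss_count))
  if (fusion_clade_size > n_tips)
    stop("fusion_clade_size must not exceed n_tips")
  if (loss_count >= fusion_clade_size)
    stop("loss_count must be smaller than fusion_clade_size: ",
         "losses cannot exceed the gained subtree")
  k <- as.integer(fusion_clade_size)
  n <- as.integer(n_tips)
  with_seed(seed, {
    if (k == n) {
      tree <- ape::rtree(n, tip.label = sprintf("fus%02d", seq_len(n)))
      fused_tips <- tree$tip.label
    } else if (k == 1L) {
      tree <- ape::rtree(n, tip.label = sprintf("bg%02d", seq_len(n)))
      fused_tips <- sample(tree$tip.label, 1L)
      tree$tip.label[tree$tip.label == fused_tips] <- "fus01"
      fused_tips <- "fus01"
    } else {
      m <- n - k + 1L
      bg <- ape::rtree(m, tip.label = sprintf("bg%02d", seq_len(m)))
      sub <- ape::rtree(k, tip.label = sprintf("fus%02d", seq_len(k)))
      sub$root.edge <- stats::runif(1, 0.1, 1)
      at <- sample(seq_len(m), 1L)
      tree <- ape::bind.tree(bg, sub, where = at)
      fused_tips <- sub$tip.label
    }
    states <- stats::setNames(integer(length(tree$tip.label)),
                              tree$tip.label)
    states[fused_tips] <- 1L
    loss_tips <- character(0)
    if (loss_count > 0) {
      loss_tips <- sample(fused_tips, loss_count)
      states[loss_tips] <- 0L
    }
    gain_node <- if (length(fused_tips) == 1L) {
      which(tree$tip.label == fused_tips)
    } else {
      ape::getMRCA(tree, fused_tips)
    }
    list(tree = tree, states = states, gain_node = gain_node,
         loss_tips = loss_tips)
  })
}

#' Kinetic ground truth for rate-data simulation
#'
#' @param KM Michaelis constant (uM).
#' @param kcat turnover number (per second).
#' @param Ki substrate-inhibition constant (uM), or `NULL` for plain
#'   Michaelis-Menten behaviour.
#' @param E0 enzyme concentration (uM); rates come out in uM/s.
#' @param noise_cv coefficient of variation of the multiplicative
#'   Gaussian rate noise.
#' @return a list of class `kinetic_truth`.
#' @examples
#' kinetic_truth(KM = 77, kcat = 0.90, E0 = 0.277)
#' @export
kinetic_truth <- function(KM, kcat, Ki = NULL, E0, noise_cv = 0.05) {
  stopifnot(is_number(KM), KM > 0, is_number(kcat), kcat > 0,
            is_number(E0), E0 > 0, is_number(noise_cv), noise_cv >= 0)
  if (!is.null(Ki)) stopifnot(is_number(Ki), Ki > 0)
  structure(list(KM = KM, kcat = kcat, Ki = Ki, E0 = E0,
                 noise_cv = noise_cv),
            class = "kinetic_truth")
}

# noiseless rate laws (uM/s with E0 in uM)
rate_law <- function(S, truth, model) {
  switch(model,
    mm = truth$kcat * truth$E0 * S / (truth$KM + S),
    substrate_inhibition = {
      if (is.null(truth$Ki))
        stop("substrate_inhibition model requires Ki in the truth")
      truth$kcat * truth$E0 * S / (truth$KM + S + S^2 / truth$Ki)
    },
    stop("unknown model: ", model)
  )
}

#' Simulate replicate initial-rate data
#'
#' Evaluates the Michaelis-Menten law `v = kcat E0 S / (KM + S)` or the
#' uncompetitive substrate-inhibition form
#' `v = kcat E0 S / (KM + S + S^2/Ki)` at each substrate concentration
#' and multiplies by Gaussian noise of constant coefficient of variation
#' (truncated at zero), emulating plate-reader assay error.
#'
#' @param truth a [kinetic_truth()].
#' @param substrate_concs substrate concentrations (uM), all positive.
#' @param n_reps replicates per concentration.
#' @param model `"mm"` or `"substrate_inhibition"`.
#' @param seed integer seed.
#' @return a data.frame (`substrate_conc_uM`, `replicate`,
#'   `rate_uM_per_s`) with the enzyme concentration attached as attribute
#'   `E0_uM`.
#' @examples
#' tr <- kinetic_truth(KM = 77, kcat = 0.90, E0 = 0.277, noise_cv = 0)
#' gen_rate_data(tr, substrate_concs = c(77, 1000), n_reps = 1)
#' @export
gen_rate_data <- function(truth, substrate_concs, n_reps = 3L,
                          model = c("mm", "substrate_inhibition"),
                          seed = 1L) {
  stopifnot(inherits(truth, "kinetic_truth"),
            is.numeric(substrate_concs), all(substrate_concs > 0),
            is_count(n_reps, positive = TRUE))
  model <- match.arg(model)
  v0 <- rate_law(substrate_concs, truth, model)
  with_seed(seed, {
    out <- data.frame(
      substrate_conc_uM = rep(substrate_concs, each = n_reps),
      replicate = rep(seq_len(n_reps), times = length(substrate_concs)),
      rate_uM_per_s = rep(v0, each = n_reps) *
        pmax(0, 1 + stats::rnorm(n_reps * length(substrate_concs),
                                 sd = truth$noise_cv))
    )
    attr(out, "E0_uM") <- truth$E0
    attr(out, "model") <- model
    out
  })
}

#' Thermal-melt ground truth
#'
#' Describes a synthetic differential-scanning-fluorimetry curve as a sum
#' of one to three logistic (two-state) unfolding transitions on a
#' uniform temperature grid, the standard 20-95 degree Celsius scan in
#' 0.5 degree steps by default.
#'
#' @param transitions data.frame with columns `midpoint_C` (strictly
#'   inside the grid), `steepness` (per degree Celsius, positive) and
#'   `amplitude` (fluorescence units).
#' @param baseline baseline fluorescence.
#' @param grid numeric `c(start, stop, step)` in degrees Celsius.
#' @param noise_sd additive Gaussian fluorescence noise.
#' @param decay_slope optional linear post-transition fluorescence decay
#'   (fluorescence units per degree) applied beyond `decay_onset_C`,
#'   emulating dye release after full unfolding.
#' @param decay_onset_C temperature at which the decay starts.
#' @return a list of class `melt_truth`.
#' @examples
#' melt_truth(data.frame(midpoint_C = c(43.8, 52.5), steepness = 0.8,
#'                       amplitude = c(800, 1500)))
#' @export
melt_truth <- function(transitions, baseline = 1000,
                       grid = c(20, 95, 0.5), noise_sd = 0,
                       decay_slope = 0, decay_onset_C = Inf) {
  stopifnot(is.data.frame(transitions),
            all(c("midpoint_C", "steepness", "amplitude") %in%
                  names(transitions)),
            nrow(transitions) >= 1, nrow(transitions) <= 3,
            is.numeric(grid), length(grid) == 3, grid[3] > 0,
            grid[2] > grid[1],
            is_number(noise_sd), noise_sd >= 0,
            is_number(baseline))
  if (any(transitions$midpoint_C <= grid[1] |
            transitions$midpoint_C >= grid[2]))
    stop("transition midpoints must lie strictly inside the grid")
  if (any(transitions$steepness <= 0)) stop("steepness must be positive")
  structure(list(transitions = transitions, baseline = baseline,
                 grid = grid, noise_sd = noise_sd,
                 decay_slope = decay_slope,
                 decay_onset_C = decay_onset_C),
            class = "melt_truth")
}

#' Simulate a thermal-shift melt curve
#'
#' Samples `baseline + sum(amplitude * logistic(steepness * (T - midpoint)))`
#' (plus the optional post-transition decay and Gaussian noise) on the
#' configured temperature grid.
#'
#' @param truth a [melt_truth()].
#' @param seed integer seed.
#' @param replicate replicate identifier stored in the output.
#' @param condition condition tag (e.g. `"apo"` or `"fucose"`).
#' @return a data.frame (`temp_C`, `fluorescence`, `replicate`,
#'   `condition`).
#' @examples
#' tr <- melt_truth(data.frame(midpoint_C = 50, steepness = 1,
#'                             amplitude = 1000))
#' head(gen_melt_curve(tr, seed = 1))
#' @export
gen_melt_curve <- function(truth, seed = 1L, replicate = 1L,
                           condition = "apo") {
  stopifnot(inherits(truth, "melt_truth"))
  temp <- seq(truth$grid[1], truth$grid[2], by = truth$grid[3])
  f <- rep(truth$baseline, length(temp))
  for (i in seq_len(nrow(truth$transitions))) {
    tr <- truth$transitions[i, ]
    f <- f + tr$amplitude /
      (1 + exp(-tr$steepness * (temp - tr$midpoint_C)))
  }
  f <- f - truth$decay_slope * pmax(0, temp - truth$decay_onset_C)
  with_seed(seed, {
    f <- f + stats::rnorm(length(temp), sd = truth$noise_sd)
    data.frame(temp_C = temp, fluorescence = f,
               replicate = replicate, condition = condition,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic conservation-census alignment
#'
#' Builds a reference-anchored multiple sequence alignment emulating the
#' structure of a putative-FKP census: a full-length reference row
#' carrying the six diagnostic residues (G75, R79, K88 in the
#' pyrophosphorylase moiety; R597, D606, D767 in the kinase moiety), a
#' configurable number of rows whose alignment to the reference begins
#' only after the exclusion boundary (gap-prefixed rows, emulating
#' N-terminally truncated entries), and clade-stratified conservation:
#' rows from clade C lose the N-terminal residues far more often than
#' rows from clades A and B, while the kinase-domain residues are nearly
#' invariant everywhere.
#'
#' @param n_rows total number of rows including the reference.
#' @param n_gap_prefixed rows whose residues all lie after the boundary.
#' @param ref_id reference row identifier.
#' @param ref_len ungapped reference length (residues); must exceed the
#'   largest diagnostic position.
#' @param positions character vector like `"G75"`: expected residue and
#'   1-based ungapped reference position.
#' @param boundary exclusion boundary as a reference position (the prefix
#'   window is positions `1..boundary`).
#' @param clade_probs named probabilities used to draw each row's clade.
#' @param p_conserved_nterm named per-clade probability that a row keeps
#'   the reference residue at each N-terminal diagnostic position.
#' @param p_conserved_cterm probability of keeping each kinase-domain
#'   diagnostic residue (all clades).
#' @param p_background probability of keeping the reference residue at
#'   non-diagnostic columns.
#' @param seed integer seed.
#' @return a list with `alignment` (named character vector of equal-width
#'   gapped rows), `clades` (named character vector), `ref_id`,
#'   `positions` and `boundary`.
#' @examples
#' cen <- gen_census_alignment(n_rows = 30, n_gap_prefixed = 3, seed = 1)
#' @export
gen_census_alignment <- function(n_rows = 186L, n_gap_prefixed = 15L,
                                 ref_id = "TxFKP_ref", ref_len = 800L,
                                 positions = c("G75", "R79", "K88",
                                               "R597", "D606", "D767"),
                                 boundary = 88L,
                                 clade_probs = c(A = 0.22, B = 0.28,
                                                 C = 0.50),
                                 p_conserved_nterm = c(A = 0.96, B = 0.96,
                                                       C = 0.30),
                                 p_conserved_cterm = 0.995,
                                 p_background = 0.8,
                                 seed = 1L) {
  stopifnot(is_count(n_rows, positive = TRUE),
            is_count(n_gap_prefixed), n_gap_prefixed < n_rows,
            is_count(ref_len, positive = TRUE),
            is_count(boundary, positive = TRUE), boundary < ref_len)
  pos <- parse_ref_positions(positions)
  if (max(pos$position) > ref_len)
    stop("ref_len must exceed the largest diagnostic position")
  nterm <- pos$position[pos$position <= boundary]
  cterm <- pos$position[pos$position > boundary]
  with_seed(seed, {
    ref <- strsplit(random_protein(ref_len), "", fixed = TRUE)[[1L]]
    ref[pos$position] <- pos$expected
    n_other <- n_rows - 1L
    clades <- sample(names(clade_probs), n_other, replace = TRUE,
                     prob = clade_probs)
    gap_rows <- sample(seq_len(n_other), n_gap_prefixed)
    rows <- vapply(seq_len(n_other), function(i) {
      chars <- ref
      keep <- stats::runif(ref_len) < p_background
      # conserved-position overrides
      keep[nterm] <- stats::runif(length(nterm)) <
        p_conserved_nterm[[clades[i]]]
      keep[cterm] <- stats::runif(length(cterm)) < p_conserved_cterm
      sub <- which(!keep)
      for (j in sub) chars[j] <- sample(setdiff(AA_ALPHABET, ref[j]), 1L)
      if (i %in% gap_rows) {
        # the row only aligns after the boundary: gap out the prefix and
        # a random additional stretch (emulating 30-200 lost residues)
        upto <- boundary + sample.int(100L, 1L)
        chars[seq_len(min(upto, ref_len - 1L))] <- "-"
      }
      paste(chars, collapse = "")
    }, "")
    aln <- c(stats::setNames(paste(ref, collapse = ""), ref_id),
             stats::setNames(rows, sprintf("FKPcensus%03d",
                                           seq_len(n_other))))
    clades <- c(stats::setNames("B", ref_id),
                stats::setNames(clades, names(aln)[-1L]))
    list(alignment = aln, clades = clades, ref_id = ref_id,
         positions = positions, boundary = as.integer(boundary))
  })
}

#' Write protein sequences to FASTA
#'
#' @param proteins data.frame with `id` and `sequence` columns, or a
#'   named character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  seqs <- if (is.data.frame(proteins)) {
    stats::setNames(proteins$sequence, proteins$id)
  } else proteins
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return a named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a hit table as TSV
#'
#' @param hits data.frame (`query_id`, `model_id`, `score`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
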