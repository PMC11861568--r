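# Synthetic-data generators. Each generator is fully seeded, returns its
# ground truth alongside the data, and is the basis of every recovery and
# calibration test in the package.

#' Configuration for a simulated arrayed siRNA screen
#'
#' The default geometry follows the common druggable-genome design: 384-well
#' plates (16 x 24), 24 plates per biological replicate, three replicates,
#' pooled siRNAs so each gene occupies exactly one well per replicate, and
#' negative-control wells scattered at random positions on every plate.
#'
#' The generative model for a measured well is multiplicative lognormal:
#' \deqn{RLU = plate\_factor \times baseline \times gene\_fold \times \epsilon}
#' where `plate_factor` is lognormal with log-sd `plate_factor_sd` (median 1),
#' `gene_fold` is 1 for controls and null genes, `activator_effect` (< 1) for
#' planted activators and `inhibitor_effect` (> 1) for planted inhibitors, and
#' `eps` is lognormal with mean 1 and coefficient of variation `noise_cv`.
#' Luminescence is positive and plate effects act multiplicatively, so the
#' ratio-to-control-median normalization cancels `plate_factor` exactly in
#' expectation.
#'
#' @param n_genes Number of targeting siRNA pools (one gene per test well).
#' @param n_plates_per_replicate Plates making up one biological replicate.
#' @param n_replicates Biological replicates (default 3).
#' @param plate_rows,plate_cols Plate format (16 x 24 = 384 wells).
#' @param n_controls_per_plate Negative-control wells per plate, position-
#'   randomized with the seed.
#' @param baseline_rlu Expected raw luminescence of a null well on an average
#'   plate, in relative luminescence units.
#' @param plate_factor_sd Lognormal sigma of the per-plate multiplicative
#'   effect (0.2 corresponds to plate medians varying by roughly +/- 20%).
#' @param noise_cv Per-well lognormal coefficient of variation.
#' @param activator_genes,inhibitor_genes Planted effect counts.
#' @param activator_effect Signal fold after silencing an activator (< 1:
#'   silencing a gene that promotes the readout lowers luminescence).
#' @param inhibitor_effect Signal fold after silencing an inhibitor (> 1).
#' @param edge_effect Optional additive row/column gradient amplitude as a
#'   fraction of `baseline_rlu` (0 = off; not part of the default world,
#'   available for robustness testing).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A validated `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes,
                              n_plates_per_replicate = 24L,
                              n_replicates = 3L,
                              plate_rows = 16L,
                              plate_cols = 24L,
                              n_controls_per_plate = 48L,
                              baseline_rlu = 1000,
                              plate_factor_sd = 0.2,
                              noise_cv = 0.1,
                              activator_genes = 0L,
                              inhibitor_genes = 0L,
                              activator_effect = 0.5,
                              inhibitor_effect = 1.8,
                              edge_effect = 0,
                              seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes", min = 1L),
    n_plates_per_replicate = check_count(n_plates_per_replicate,
                                         "n_plates_per_replicate", min = 1L),
    n_replicates = check_count(n_replicates, "n_replicates", min = 1L),
    plate_rows = check_count(plate_rows, "plate_rows", min = 1L),
    plate_cols = check_count(plate_cols, "plate_cols", min = 1L),
    n_controls_per_plate = check_count(n_controls_per_plate,
                                       "n_controls_per_plate", min = 0L),
    baseline_rlu = check_positive(baseline_rlu, "baseline_rlu"),
    plate_factor_sd = check_positive(plate_factor_sd, "plate_factor_sd"),
    noise_cv = check_positive(noise_cv, "noise_cv"),
    activator_genes = check_count(activator_genes, "activator_genes"),
    inhibitor_genes = check_count(inhibitor_genes, "inhibitor_genes"),
    activator_effect = check_positive(activator_effect, "activator_effect"),
    inhibitor_effect = check_positive(inhibitor_effect, "inhibitor_effect"),
    edge_effect = as.numeric(edge_effect),
    seed = check_count(seed, "seed")
  )
  n_wells <- cfg$plate_rows * cfg$plate_cols
  if (cfg$n_controls_per_plate >= n_wells) {
    stop_validation("n_controls_per_plate must leave at least one test well")
  }
  capacity <- cfg$n_plates_per_replicate * (n_wells - cfg$n_controls_per_plate)
  if (cfg$n_genes > capacity) {
    stop_validation("insufficient test wells: ", cfg$n_genes, " genes but only ",
                    capacity, " test wells per replicate")
  }
  if (cfg$activator_genes + cfg$inhibitor_genes > cfg$n_genes) {
    stop_validation("planted activator + inhibitor genes exceed n_genes")
  }
  if (cfg$activator_effect >= 1) {
    stop_validation("activator_effect must be < 1 (silencing lowers the signal)")
  }
  if (cfg$inhibitor_effect <= 1) {
    stop_validation("inhibitor_effect must be > 1 (silencing raises the signal)")
  }
  structure(cfg, class = "screen_sim_config")
}

control_types <- function() c("GFP", "Scrambled", "AllStars")

#' Simulate an arrayed luminescent siRNA screen with ground truth
#'
#' Generates the plate layout (negative controls at seeded-random positions,
#' genes assigned one well each, surplus wells empty), then draws raw RLU for
#' every measured well of every replicate under the model described in
#' [screen_sim_config()]. Replicates share the plate layout (the physical
#' library plates are reused across biological replicates) but draw
#' independent plate factors and noise.
#'
#' @param config A [screen_sim_config()].
#' @return A list with components `screen` (a `screen_dataset`: `$platemap`
#'   with plate_id, well, role, gene_id, control_type and `$measurements`
#'   with plate_id, well, replicate, rlu) and `truth` (data frame gene_id,
#'   class in activator/inhibitor/null, fold).
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_sim_config")) {
    stop_validation("config must be created by screen_sim_config()")
  }
  wells <- well_names(config$plate_rows, config$plate_cols)
  n_wells <- length(wells)
  plate_ids <- sprintf("P%02d", seq_len(config$n_plates_per_replicate))
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))

  with_seed(config$seed, {
    # Layout: control positions and types per plate, then sequential gene fill.
    platemap <- do.call(rbind, lapply(plate_ids, function(p) {
      ctrl <- sort(sample.int(n_wells, config$n_controls_per_plate))
      role <- rep("test", n_wells)
      role[ctrl] <- "negative_control"
      ctype <- rep(NA_character_, n_wells)
      ctype[ctrl] <- sample(control_types(), length(ctrl), replace = TRUE)
      data.frame(plate_id = p, well = wells, role = role,
                 gene_id = NA_character_, control_type = ctype,
                 stringsAsFactors = FALSE)
    }))
    test_idx <- which(platemap$role == "test")
    platemap$gene_id[test_idx[seq_along(gene_ids)]] <- gene_ids
    platemap$role[test_idx[-seq_along(gene_ids)]] <- "empty"

    # Planted truth: disjoint activator/inhibitor sets at seeded-random genes.
    class <- rep("null", config$n_genes)
    planted <- sample(config$n_genes, config$activator_genes + config$inhibitor_genes)
    class[planted[seq_len(config$activator_genes)]] <- "activator"
    if (config$inhibitor_genes > 0) {
      class[planted[config$activator_genes + seq_len(config$inhibitor_genes)]] <- "inhibitor"
    }
    fold <- ifelse(class == "activator", config$activator_effect,
                   ifelse(class == "inhibitor", config$inhibitor_effect, 1))
    truth <- data.frame(gene_id = gene_ids, class = class, fold = fold,
                        stringsAsFactors = FALSE)

    measured <- platemap[platemap$role != "empty", , drop = FALSE]
    well_fold <- ifelse(measured$role == "test",
                        truth$fold[match(measured$gene_id, truth$gene_id)], 1)
    sdlog <- sqrt(log1p(config$noise_cv^2))
    edge <- if (config$edge_effect != 0) {
      ri <- match(substr(measured$well, 1, 1), LETTERS)
      ci <- as.integer(sub("^[A-Z]", "", measured$well))
      config$edge_effect * config$baseline_rlu *
        ((ri - 1) / (config$plate_rows - 1) + (ci - 1) / (config$plate_cols - 1)) / 2
    } else 0

    measurements <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      rlu <- numeric(nrow(measured))
      for (p in plate_ids) {
        idx <- which(measured$plate_id == p)
        plate_factor <- stats::rlnorm(1, 0, config$plate_factor_sd)
        noise <- stats::rlnorm(length(idx), -sdlog^2 / 2, sdlog)
        rlu[idx] <- plate_factor * config$baseline_rlu * well_fold[idx] * noise
      }
      data.frame(plate_id = measured$plate_id, well = measured$well,
                 replicate = r, rlu = rlu + edge, stringsAsFactors = FALSE)
    }))

    screen <- new_screen_dataset(platemap, measurements,
                                 config$plate_rows, config$plate_cols)
    list(screen = screen, truth = truth)
  })
}

#' Simulate a gene-by-sample read-count table with a known expressed set
#'
#' Expressed genes draw negative-binomial counts with a high mean so their
#' median sits comfortably above the expression filter boundary; background
#' genes draw from a low-mean distribution whose median sits comfortably
#' below it.
#'
#' @param n_genes Number of genes.
#' @param n_samples Samples (default 3, as for triplicate RNA-seq).
#' @param expressed_fraction Fraction of genes planted as expressed.
#' @param gene_ids Optional identifiers (default `GENE0001` ...), so the
#'   table can share the id space of a simulated screen.
#' @param expressed_mu,background_mu Negative-binomial means of the two
#'   populations (defaults 500 and 4 reads).
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @param seed Integer seed.
#' @return List with `counts` (data.frame gene_id + sample columns) and
#'   `expressed` (character vector of truth-expressed gene ids).
#' @export
simulate_counts <- function(n_genes, n_samples = 3L, expressed_fraction = 0.5,
                            gene_ids = NULL, expressed_mu = 500,
                            background_mu = 4, nb_size = 8, seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  expressed_fraction <- check_fraction(expressed_fraction, "expressed_fraction")
  if (is.null(gene_ids)) gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
  if (length(gene_ids) != n_genes || anyDuplicated(gene_ids)) {
    stop_validation("gene_ids must be ", n_genes, " unique identifiers")
  }
  with_seed(seed, {
    n_expr <- round(expressed_fraction * n_genes)
    expressed <- sort(sample(gene_ids, n_expr))
    mu <- ifelse(gene_ids %in% expressed, expressed_mu, background_mu)
    counts <- matrix(stats::rnbinom(n_genes * n_samples,
                                    mu = rep(mu, n_samples), size = nb_size),
                     nrow = n_genes)
    df <- data.frame(gene_id = gene_ids, counts, stringsAsFactors = FALSE)
    names(df)[-1] <- sprintf("sample_%d", seq_len(n_samples))
    list(counts = df, expressed = expressed)
  })
}

#' Simulate a GMT gene-set library with one planted enriched term
#'
#' All terms draw members at random from the universe except the designated
#' first term, which is constructed to share `enriched_overlap` genes with
#' the supplied query.
#'
#' @param n_terms Number of gene sets.
#' @param term_size_range Inclusive integer range of set sizes.
#' @param universe Character vector of gene symbols.
#' @param query Optional query gene set the planted term is enriched in.
#' @param enriched_overlap Overlap between the planted term and the query.
#' @param seed Integer seed.
#' @param path Optional path; when given the library is also written as GMT.
#' @return List with `library` (named list of member vectors), `descriptions`
#'   and `enriched_term` (name of the planted term, `NA` if none).
#' @export
simulate_gmt <- function(n_terms, term_size_range = c(10L, 50L), universe,
                         query = NULL, enriched_overlap = NULL, seed = 1L,
                         path = NULL) {
  n_terms <- check_count(n_terms, "n_terms", min = 1L)
  universe <- unique(toupper(universe))
  if (length(universe) == 0) stop_validation("universe must be nonempty")
  lo <- check_count(term_size_range[1], "term_size_range[1]", min = 1L)
  hi <- check_count(term_size_range[2], "term_size_range[2]", min = lo)
  if (hi > length(universe)) {
    stop_validation("term size ", hi, " exceeds universe size ", length(universe))
  }
  with_seed(seed, {
    # sample.int avoids the sample(x) scalar pitfall when lo == hi
    sizes <- lo + sample.int(hi - lo + 1L, n_terms, replace = TRUE) - 1L
    lib <- lapply(sizes, function(k) sort(sample(universe, k)))
    names(lib) <- sprintf("TERM_%03d", seq_len(n_terms))
    enriched_term <- NA_character_
    if (!is.null(query) && !is.null(enriched_overlap)) {
      query <- unique(toupper(query))
      k <- check_count(enriched_overlap, "enriched_overlap")
      size <- sizes[1]
      if (k > min(size, length(query))) {
        stop_validation("enriched_overlap exceeds term or query size")
      }
      inside <- sample(intersect(query, universe), k)
      pool <- setdiff(universe, query)
      if (size - k > length(pool)) {
        stop_validation("universe too small to fill the planted term")
      }
      lib[[1]] <- sort(c(inside, sample(pool, size - k)))
      names(lib)[1] <- "PLANTED_TERM"
      enriched_term <- "PLANTED_TERM"
    }
    descriptions <- stats::setNames(sprintf("synthetic gene set %d",
                                            seq_len(n_terms)), names(lib))
    out <- list(library = lib, descriptions = descriptions,
                enriched_term = enriched_term)
    if (!is.null(path)) write_gmt(out$library, path, descriptions = descriptions)
    out
  })
}

#' Configuration for a simulated TMT phosphosite table
#'
#' @param n_sites Number of phosphosites.
#' @param n_regulated Sites planted with a true group difference; regulation
#'   is planted only on sites not flagged reverse or contaminant (decoy and
#'   contaminant identifications carry no biology).
#' @param n_replicates Biological replicates per condition (default 4).
#' @param group_difference True mean log2 difference (stimulated - control);
#'   planted with random sign per site.
#' @param within_group_sd Replicate-to-replicate sd on the log2 scale.
#' @param frac_reverse,frac_contaminant Fractions of sites flagged as decoy /
#'   contaminant identifications (disjoint sets).
#' @param loc_prob_beta Beta(shape1, shape2) parameters of the localization
#'   probability distribution (default Beta(5, 1): ~3% of sites below 0.5).
#' @param score_diff_gamma Gamma(shape, scale) parameters of the score
#'   difference distribution (default Gamma(2, 20): ~3% of sites below 5).
#' @param base_log2_mean,base_log2_sd Site baseline abundance distribution
#'   on the log2 scale.
#' @param seed Integer seed.
#' @return A validated `phospho_sim_config` list.
#' @export
phospho_sim_config <- function(n_sites, n_regulated = 0L, n_replicates = 4L,
                               group_difference = 1.0, within_group_sd = 0.2,
                               frac_reverse = 0.01, frac_contaminant = 0.01,
                               loc_prob_beta = c(5, 1),
                               score_diff_gamma = c(2, 20),
                               base_log2_mean = 20, base_log2_sd = 2,
                               seed = 1L) {
  cfg <- list(
    n_sites = check_count(n_sites, "n_sites", min = 1L),
    n_regulated = check_count(n_regulated, "n_regulated"),
    n_replicates = check_count(n_replicates, "n_replicates", min = 2L),
    group_difference = as.numeric(group_difference),
    within_group_sd = check_positive(within_group_sd, "within_group_sd"),
    frac_reverse = check_fraction(frac_reverse, "frac_reverse"),
    frac_contaminant = check_fraction(frac_contaminant, "frac_contaminant"),
    loc_prob_beta = as.numeric(loc_prob_beta),
    score_diff_gamma = as.numeric(score_diff_gamma),
    base_log2_mean = as.numeric(base_log2_mean),
    base_log2_sd = check_positive(base_log2_sd, "base_log2_sd"),
    seed = check_count(seed, "seed")
  )
  if (cfg$n_regulated > cfg$n_sites) {
    stop_validation("n_regulated must not exceed n_sites")
  }
  if (cfg$frac_reverse + cfg$frac_contaminant > 1) {
    stop_validation("frac_reverse + frac_contaminant must not exceed 1")
  }
  structure(cfg, class = "phospho_sim_config")
}

#' Simulate a wide TMT phosphosite intensity table with ground truth
#'
#' @param config A [phospho_sim_config()].
#' @return List with `table` (wide data.frame: gene, protein, position,
#'   residue, localization_prob, score_diff, reverse, contaminant, and raw
#'   intensity columns `stim_1..n` / `ctrl_1..n`) and `truth` (site_id,
#'   regulated, log2_effect, reverse, contaminant).
#' @export
simulate_phospho <- function(config) {
  if (!inherits(config, "phospho_sim_config")) {
    stop_validation("config must be created by phospho_sim_config()")
  }
  n <- config$n_sites
  r <- config$n_replicates
  with_seed(config$seed, {
    gene <- sprintf("PGENE%04d", seq_len(n))
    position <- sample(5:1200, n, replace = TRUE)
    residue <- sample(c("S", "T", "Y"), n, replace = TRUE,
                      prob = c(0.75, 0.20, 0.05))
    loc_prob <- stats::rbeta(n, config$loc_prob_beta[1], config$loc_prob_beta[2])
    score_diff <- stats::rgamma(n, shape = config$score_diff_gamma[1],
                                scale = config$score_diff_gamma[2])
    n_rev <- round(config$frac_reverse * n)
    n_con <- round(config$frac_contaminant * n)
    flagged <- sample.int(n, min(n, n_rev + n_con))
    reverse <- seq_len(n) %in% flagged[seq_len(n_rev)]
    contaminant <- seq_len(n) %in% flagged[n_rev + seq_len(min(n_con, length(flagged) - n_rev))]

    clean <- which(!reverse & !contaminant)
    if (config$n_regulated > length(clean)) {
      stop_validation("not enough unflagged sites to plant ", config$n_regulated,
                      " regulated sites")
    }
    reg_idx <- sample(clean, config$n_regulated)
    effect <- numeric(n)
    effect[reg_idx] <- sample(c(-1, 1), config$n_regulated, replace = TRUE) *
      config$group_difference

    base <- stats::rnorm(n, config$base_log2_mean, config$base_log2_sd)
    stim <- base + effect + matrix(stats::rnorm(n * r, 0, config$within_group_sd), n, r)
    ctrl <- base + matrix(stats::rnorm(n * r, 0, config$within_group_sd), n, r)

    tab <- data.frame(gene = gene, protein = sprintf("PROT%04d", seq_len(n)),
                      position = position, residue = residue,
                      localization_prob = loc_prob, score_diff = score_diff,
                      reverse = reverse, contaminant = contaminant,
                      2^stim, 2^ctrl, stringsAsFactors = FALSE)
    names(tab)[8 + seq_len(r)] <- sprintf("stim_%d", seq_len(r))
    names(tab)[8 + r + seq_len(r)] <- sprintf("ctrl_%d", seq_len(r))
    truth <- data.frame(site_id = sprintf("%s(%d)", gene, position),
                        regulated = effect != 0, log2_effect = effect,
                        reverse = reverse, contaminant = contaminant,
                        stringsAsFactors = FALSE)
    list(table = tab, truth = truth)
  })
}
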