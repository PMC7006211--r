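#' Midgut tissue labels
#'
#' The five tissues of the atlas: the four midgut compartments along the
#' anterior-posterior axis (the microscopic hindgut is included with M4) and
#' the remaining non-midgut carcass.
#' @export
MIDGUT_TISSUES <- c("M1", "M2", "M3", "M4", "carcass")

#' Expression archetypes emulated by the generator
#'
#' Eight archetypal expression patterns along the midgut -- four
#' single-compartment peaks, a monotone anterior-to-posterior increase and
#' decrease, an anterior (M1-M3) and a posterior (M2-M4) block -- plus a flat
#' background class that carries no compartment signal.
#' @export
ARCHETYPES <- c("M1", "M2", "M3", "M4",
                "increasing", "decreasing", "anterior", "posterior", "flat")

# mean TPM profile of each archetype over (M1, M2, M3, M4, carcass),
# before the per-gene abundance scale factor
archetype_profiles <- function() {
  p <- rbind(
    M1         = c(100, 0.5, 0.5, 0.5, 0.5),
    M2         = c(0.5, 100, 0.5, 0.5, 0.5),
    M3         = c(0.5, 0.5, 100, 0.5, 0.5),
    M4         = c(0.5, 0.5, 0.5, 100, 0.5),
    increasing = c(  2,  20,  60, 100,   5),
    decreasing = c(100,  60,  20,   2,   5),
    anterior   = c( 80,  80,  80, 0.5,   5),
    posterior  = c(0.5,  80,  80,  80,   5),
    flat       = c( 20,  20,  20,  20,  20)
  )
  colnames(p) <- MIDGUT_TISSUES
  p
}

#' Describe a gene family to plant into the synthetic catalog
#'
#' @param name family name (e.g. "CYP", "SP", "AAAP").
#' @param type `"p450"` (members carry the P450 heme-ligand motif) or
#'   `"transporter"` (members carry `tm_count` hydrophobic stretches that the
#'   Kyte-Doolittle caller reports as transmembrane segments).
#' @param n_members number of family members planted into the unigene catalog.
#' @param length_range two integers, min/max member length in residues.
#' @param tm_count number of transmembrane helices in the template
#'   (transporter type only).
#' @param panel_size reference-panel members emitted per reference species.
#' @return a `planted_family` list.
#' @export
planted_family <- function(name, type = c("transporter", "p450"),
                           n_members = 6, length_range = c(400, 500),
                           tm_count = 3, panel_size = 5) {
  type <- match.arg(type)
  if (n_members < 1) stopf("planted_family '%s': n_members must be >= 1", name)
  if (length(length_range) != 2 || length_range[1] > length_range[2])
    stopf("planted_family '%s': invalid length_range", name)
  structure(list(name = name, type = type, n_members = n_members,
                 length_range = as.integer(length_range),
                 tm_count = as.integer(tm_count),
                 panel_size = as.integer(panel_size)),
            class = "planted_family")
}

default_planted_families <- function() {
  list(
    planted_family("CYP",  "p450",        n_members = 8,
                   length_range = c(440, 520), panel_size = 6),
    planted_family("SP",   "transporter", n_members = 8,
                   length_range = c(420, 500), tm_count = 6, panel_size = 5),
    planted_family("AAAP", "transporter", n_members = 6,
                   length_range = c(380, 460), tm_count = 4, panel_size = 5)
  )
}

#' Specify a synthetic midgut-atlas dataset
#'
#' Defines the study conditions the generator emulates: catalog size and
#' redundancy, contaminant load, the mixture of expression archetypes along
#' the gut, replicate noise, and the gene families planted for the
#' family-annotation stage.
#'
#' @param n_genes number of background genes in the catalog (planted family
#'   members are appended on top of these).
#' @param isoform_rate fraction of genes emitted with more than one isoform.
#' @param contained_rate fraction of genes whose representative protein is an
#'   exact substring of another gene's protein (exercises containment dedup).
#' @param contaminant_frac fraction of genes flagged as bacterial/plant-like
#'   via the taxon-annotation table.
#' @param archetype_weights named probability vector over [ARCHETYPES]
#'   (the eight patterns plus `"flat"`); must sum to 1.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   replicate noise on TPM.
#' @param replicates biological replicates per tissue.
#' @param planted_families list of [planted_family()] descriptions.
#' @param seed integer seed; a fixed seed makes every generator output
#'   byte-identical across runs.
#' @return a validated `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_genes = 2000,
                           isoform_rate = 0.3,
                           contained_rate = 0.05,
                           contaminant_frac = 0.09,
                           archetype_weights = NULL,
                           noise_cv = 0.2,
                           replicates = 4,
                           planted_families = default_planted_families(),
                           seed = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1 ||
      n_genes != round(n_genes))
    stopf("invalid spec field 'n_genes': must be a positive integer")
  for (f in c("isoform_rate", "contained_rate", "contaminant_frac")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stopf("invalid spec field '%s': must be a fraction in [0, 1]", f)
  }
  if (is.null(archetype_weights)) {
    archetype_weights <- c(rep(0.07, 8), 0.44)
    names(archetype_weights) <- ARCHETYPES
  }
  if (is.null(names(archetype_weights)) ||
      !all(names(archetype_weights) %in% ARCHETYPES))
    stopf("invalid spec field 'archetype_weights': names must be in ARCHETYPES")
  if (any(archetype_weights < 0) ||
      abs(sum(archetype_weights) - 1) > 1e-8)
    stopf("invalid spec field 'archetype_weights': must be non-negative and sum to 1")
  if (!is.numeric(noise_cv) || length(noise_cv) != 1 || noise_cv < 0)
    stopf("invalid spec field 'noise_cv': must be a non-negative number")
  if (!is.numeric(replicates) || replicates < 1)
    stopf("invalid spec field 'replicates': must be a positive integer")
  if (!is.list(planted_families) ||
      !all(vapply(planted_families, inherits, TRUE, "planted_family")))
    stopf("invalid spec field 'planted_families': must be a list of planted_family objects")
  if (!is.numeric(seed) || length(seed) != 1)
    stopf("invalid spec field 'seed': must be a single integer")
  structure(list(n_genes = as.integer(n_genes),
                 isoform_rate = isoform_rate,
                 contained_rate = contained_rate,
                 contaminant_frac = contaminant_frac,
                 archetype_weights = archetype_weights[
                   intersect(ARCHETYPES, names(archetype_weights))],
                 noise_cv = noise_cv,
                 replicates = as.integer(replicates),
                 planted_families = planted_families,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# P450 heme-ligand motif instance matching F-x-x-G-x-[RH]-x-C-x-G
P450_MOTIF_REGEX <- "F..G.[RH].C.G"
P450_MOTIF_INSTANCE <- "FSEGKRVCIG"

HYDROPHOBIC_AA <- c("L", "I", "V", "F", "A")
HYDROPHILIC_AA <- c("D", "E", "K", "R", "N", "Q", "S", "G", "P", "T")

# replace the leading F of any chance P450-motif occurrence so decoys and
# non-P450 genes never match the domain check
scrub_p450_motif <- function(seqs) {
  repeat {
    hit <- regexpr(P450_MOTIF_REGEX, seqs)
    idx <- which(hit > 0)
    if (length(idx) == 0) return(seqs)
    for (i in idx) substr(seqs[i], hit[i], hit[i]) <- "D"
  }
}

#' Generate a synthetic unigene catalog
#'
#' Emits Trinity-style protein records (gene/isoform accessions such as
#' `TRINITY_DN1000_c0_g1_i1`), a taxon-annotation table marking a configurable
#' fraction of genes as bacterial/plant-like (best-hit e-value below 1e-05),
#' and the planted truth labels. A configurable fraction of genes have
#' multiple isoforms of distinct lengths, and another fraction are exact
#' substrings of longer records, so the downstream reduction steps have work
#' to do.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `records` (accession, gene_id, isoform_id, sequence,
#'   length), `taxa` (gene_id, taxon_group, e_value) and `truth` (per-gene
#'   archetype, contaminant and containment labels).
#' @export
gen_unigene_catalog <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_genes
    gene_ids <- sprintf("DN%d_c0_g1", seq_len(n) + 999L)

    w <- spec$archetype_weights
    archetype <- sample(names(w), n, replace = TRUE, prob = w)

    contaminant <- stats::runif(n) < spec$contaminant_frac
    # bacterial-like genes concentrate in the symbiont-bearing M4 region
    if (any(contaminant)) {
      bias <- stats::runif(sum(contaminant))
      arch_cont <- archetype[contaminant]
      arch_cont[bias < 0.70] <- "M4"
      arch_cont[bias >= 0.70 & bias < 0.85] <- "flat"
      archetype[contaminant] <- arch_cont
    }

    lens <- sample(150:600, n, replace = TRUE)
    seqs <- vapply(lens, random_protein, character(1))

    # containment: overwrite a fraction of genes with substrings of longer hosts
    contained <- rep(FALSE, n)
    n_contained <- round(spec$contained_rate * n)
    if (n_contained > 0) {
      ord <- order(lens, decreasing = TRUE)
      hosts <- ord[seq_len(min(n, max(n_contained, 50)))]
      victims <- sample(setdiff(seq_len(n), hosts[seq_len(n_contained)]),
                        n_contained)
      for (j in seq_len(n_contained)) {
        v <- victims[j]; h <- hosts[j]
        sub_len <- max(100L, lens[h] - sample(40:80, 1))
        start <- sample(seq_len(lens[h] - sub_len + 1), 1)
        seqs[v] <- substr(seqs[h], start, start + sub_len - 1L)
        lens[v] <- sub_len
        contained[v] <- TRUE
      }
    }
    seqs <- scrub_p450_motif(seqs)

    # isoforms: longest isoform is the canonical sequence; extra isoforms are
    # shorter truncations with distinct lengths
    has_iso <- stats::runif(n) < spec$isoform_rate
    rec <- vector("list", n)
    for (i in seq_len(n)) {
      n_iso <- if (has_iso[i] && lens[i] > 160) sample(2:3, 1) else 1L
      iso_seqs <- seqs[i]
      if (n_iso > 1) {
        sub_lens <- unique(sample(100:(lens[i] - 10L), n_iso - 1L))
        iso_seqs <- c(iso_seqs, substr(rep(seqs[i], length(sub_lens)), 1, sub_lens))
      }
      rec[[i]] <- data.frame(
        accession = sprintf("TRINITY_%s_i%d", gene_ids[i], seq_along(iso_seqs)),
        gene_id = gene_ids[i],
        isoform_id = sprintf("i%d", seq_along(iso_seqs)),
        sequence = iso_seqs,
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rec)
    records$length <- nchar(records$sequence)

    # taxon annotation: contaminants get strong bacterial/plant hits; most
    # clean genes get arthropod hits; a few get weak (above-threshold)
    # bacterial hits that the filter must keep
    taxa <- data.frame(gene_id = character(0), taxon_group = character(0),
                       e_value = numeric(0), stringsAsFactors = FALSE)
    if (any(contaminant)) {
      idx <- which(contaminant)
      taxa <- rbind(taxa, data.frame(
        gene_id = gene_ids[idx],
        taxon_group = sample(c("bacteria", "plants"), length(idx),
                             replace = TRUE, prob = c(0.8, 0.2)),
        e_value = 10^stats::runif(length(idx), -40, -6),
        stringsAsFactors = FALSE))
    }
    clean <- which(!contaminant)
    u <- stats::runif(length(clean))
    arth <- clean[u < 0.8]
    weak <- clean[u >= 0.95]
    if (length(arth))
      taxa <- rbind(taxa, data.frame(
        gene_id = gene_ids[arth], taxon_group = "arthropoda",
        e_value = 10^stats::runif(length(arth), -100, -10),
        stringsAsFactors = FALSE))
    if (length(weak))
      taxa <- rbind(taxa, data.frame(
        gene_id = gene_ids[weak], taxon_group = "bacteria",
        e_value = 10^stats::runif(length(weak), -4, -2),
        stringsAsFactors = FALSE))
    taxa <- taxa[order(taxa$gene_id), , drop = FALSE]
    rownames(taxa) <- NULL

    truth <- list(
      archetype = stats::setNames(archetype, gene_ids),
      contaminant = stats::setNames(contaminant, gene_ids),
      contained = stats::setNames(contained, gene_ids),
      family = stats::setNames(rep(NA_character_, n), gene_ids)
    )
    list(records = records, taxa = taxa, truth = truth)
  })
}

# build one family: a conserved ancestor carrying the template, from which
# panel and planted members are derived by mutating non-template positions
build_family <- function(fam, mut_rate = 0.12) {
  core_len <- fam$length_range[1]
  if (fam$type == "p450") {
    core <- strsplit(random_protein(core_len), "")[[1]]
    motif <- strsplit(P450_MOTIF_INSTANCE, "")[[1]]
    pos <- floor(core_len * 0.75)
    if (pos + length(motif) - 1 > core_len)
      stopf("family '%s': template length exceeds sequence length", fam$name)
    core[pos:(pos + length(motif) - 1)] <- motif
    template_mask <- rep(FALSE, core_len)
    template_mask[pos:(pos + length(motif) - 1)] <- TRUE
  } else {
    tm_len <- 21L; linker_len <- 30L
    needed <- fam$tm_count * tm_len + (fam$tm_count + 1L) * linker_len
    if (needed > core_len)
      stopf("family '%s': template length exceeds sequence length", fam$name)
    core <- character(0); template_mask <- logical(0)
    pad0 <- linker_len + (core_len - needed)
    core <- sample(HYDROPHILIC_AA, pad0, replace = TRUE)
    template_mask <- rep(FALSE, pad0)
    for (k in seq_len(fam$tm_count)) {
      core <- c(core, sample(HYDROPHOBIC_AA, tm_len, replace = TRUE))
      template_mask <- c(template_mask, rep(TRUE, tm_len))
      core <- c(core, sample(HYDROPHILIC_AA, linker_len, replace = TRUE))
      template_mask <- c(template_mask, rep(FALSE, linker_len))
    }
    core_len <- length(core)
  }

  make_member <- function(target_len) {
    s <- core
    mut <- which(!template_mask & stats::runif(length(s)) < mut_rate)
    if (length(mut))
      s[mut] <- sample(AA_ALPHABET, length(mut), replace = TRUE,
                       prob = AA_BACKGROUND)
    pad <- max(0L, target_len - length(s))
    if (pad > 0)
      s <- c(s, sample(HYDROPHILIC_AA, pad, replace = TRUE))
    seq1 <- paste(s, collapse = "")
    if (fam$type != "p450") seq1 <- scrub_p450_motif(seq1)
    seq1
  }

  target_lens <- function(k)
    sample(seq(fam$length_range[1], fam$length_range[2]), k, replace = TRUE)

  panel <- list()
  for (sp in c("Hsap", "Dmel")) {
    lens <- pmax(core_len, target_lens(fam$panel_size))
    panel[[sp]] <- stats::setNames(
      vapply(lens, make_member, character(1)),
      sprintf("%s_%s_%d", sp, fam$name, seq_len(fam$panel_size)))
  }
  members <- vapply(pmax(core_len, target_lens(fam$n_members)),
                    make_member, character(1))
  list(members = members, panel = panel)
}

#' Plant gene-family members and emit reference panels
#'
#' Appends family-member genes to the catalog (each containing its family's
#' template: a P450 heme-ligand motif, or `tm_count` hydrophobic stretches
#' long enough to be called as transmembrane segments) and builds the
#' two-reference-species panels used by the family-annotation stage. Decoy
#' (background) genes never contain a P450 motif.
#'
#' @param spec a [synthetic_spec()].
#' @param catalog output of [gen_unigene_catalog()]; planted records are
#'   appended to it.
#' @return the catalog with `records`/`truth` extended, plus `panels`: a named
#'   list of `family_panel` objects.
#' @export
gen_family_sequences <- function(spec, catalog) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed + 1L, {
    panels <- list()
    next_dn <- 1000L + spec$n_genes
    records <- catalog$records
    truth <- catalog$truth
    fam_arch <- c(p450 = "anterior", transporter = "M4")
    for (fam in spec$planted_families) {
      built <- build_family(fam)
      gene_ids <- sprintf("DN%d_c0_g1", next_dn + seq_along(built$members))
      next_dn <- next_dn + length(built$members)
      add <- data.frame(
        accession = sprintf("TRINITY_%s_i1", gene_ids),
        gene_id = gene_ids, isoform_id = "i1",
        sequence = built$members,
        length = nchar(built$members), stringsAsFactors = FALSE)
      records <- rbind(records, add)
      arch <- fam_arch[[fam$type]]
      truth$archetype <- c(truth$archetype,
                           stats::setNames(rep(arch, length(gene_ids)), gene_ids))
      truth$contaminant <- c(truth$contaminant,
                             stats::setNames(rep(FALSE, length(gene_ids)), gene_ids))
      truth$contained <- c(truth$contained,
                           stats::setNames(rep(FALSE, length(gene_ids)), gene_ids))
      truth$family <- c(truth$family,
                        stats::setNames(rep(fam$name, length(gene_ids)), gene_ids))
      panels[[fam$name]] <- family_panel(fam$name, built$panel,
                                         type = fam$type,
                                         tm_min = if (fam$type == "transporter") 3L else 0L)
    }
    list(records = records, taxa = catalog$taxa, truth = truth, panels = panels)
  })
}

#' Generate replicate TPM expression values
#'
#' Each gene's mean profile over the five tissues follows its planted
#' archetype scaled by a per-gene abundance factor; replicate values are the
#' mean times multiplicative lognormal noise with the requested coefficient
#' of variation (mean 1, so `noise_cv = 0` reproduces the archetype means
#' exactly).
#'
#' @param truth truth list from the catalog generators (uses `$archetype`).
#' @param replicates replicates per tissue (>= 2).
#' @param noise_cv coefficient of variation of replicate noise.
#' @param seed integer seed.
#' @return numeric matrix, genes x (tissue_replicate) columns named
#'   `M1_1 ... carcass_<r>`.
#' @export
gen_expression <- function(truth, replicates = 4, noise_cv = 0.2, seed = 1) {
  if (replicates < 2) stopf("gen_expression: replicates must be >= 2")
  arch <- truth$archetype
  profs <- archetype_profiles()
  bad <- setdiff(unique(arch), rownames(profs))
  if (length(bad)) stopf("unknown archetype label: %s", paste(bad, collapse = ", "))
  with_seed(seed, {
    n <- length(arch)
    scale_f <- stats::rlnorm(n, meanlog = 0, sdlog = 0.8)
    means <- profs[arch, , drop = FALSE] * scale_f
    cols <- as.vector(t(outer(MIDGUT_TISSUES, seq_len(replicates),
                              function(t, r) paste(t, r, sep = "_"))))
    m <- matrix(0, nrow = n, ncol = length(cols),
                dimnames = list(names(arch), cols))
    for (ti in seq_along(MIDGUT_TISSUES)) {
      for (r in seq_len(replicates)) {
        col <- paste(MIDGUT_TISSUES[ti], r, sep = "_")
        if (noise_cv > 0) {
          s <- sqrt(log(1 + noise_cv^2))
          noise <- stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
        } else noise <- rep(1, n)
        m[, col] <- means[, ti] * noise
      }
    }
    m
  })
}

#' Generate a term-annotation table with planted enrichments
#'
#' For each non-flat archetype a "marker" PFAM-like term is given to half of
#' that archetype's genes plus a 1% background, so groups recovered by
#' clustering or Top-N selection are genuinely enriched for their marker term.
#' Null terms covering random gene subsets are added as negative material.
#'
#' @param truth truth list (uses `$archetype`).
#' @param seed integer seed.
#' @param n_null number of non-enriched background terms.
#' @return list with `terms` (gene_id, term_id, term_kind) and
#'   `enriched_terms` (archetype -> its planted marker term).
#' @export
gen_term_annotation <- function(truth, seed = 1, n_null = 20) {
  arch <- truth$archetype
  genes <- names(arch)
  with_seed(seed + 2L, {
    rows <- list()
    marker <- character(0)
    planted_arch <- setdiff(ARCHETYPES, "flat")
    for (i in seq_along(planted_arch)) {
      a <- planted_arch[i]
      term <- sprintf("PF9%03d", i)
      marker[a] <- term
      members <- genes[arch == a]
      inside <- members[stats::runif(length(members)) < 0.5]
      outside <- setdiff(genes, members)
      outside <- outside[stats::runif(length(outside)) < 0.01]
      ids <- c(inside, outside)
      if (length(ids))
        rows[[term]] <- data.frame(gene_id = ids, term_id = term,
                                   term_kind = "PFAM", stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_null)) {
      term <- sprintf("GO:%07d", j)
      frac <- stats::runif(1, 0.02, 0.05)
      ids <- genes[stats::runif(length(genes)) < frac]
      if (length(ids))
        rows[[term]] <- data.frame(gene_id = ids, term_id = term,
                                   term_kind = "GO", stringsAsFactors = FALSE)
    }
    terms <- do.call(rbind, rows)
    rownames(terms) <- NULL
    list(terms = terms, enriched_terms = marker)
  })
}

#' Simulate a complete synthetic midgut-atlas dataset
#'
#' Composes the catalog, planted-family, term-annotation and expression
#' generators into one object every downstream stage accepts directly.
#'
#' @param spec a [synthetic_spec()].
#' @return an `atlas_sim` list: `records`, `taxa`, `terms`, `panels`,
#'   `expression`, `truth`, `spec`.
#' @export
simulate_atlas <- function(spec) {
  cat0 <- gen_unigene_catalog(spec)
  cat1 <- gen_family_sequences(spec, cat0)
  ann <- gen_term_annotation(cat1$truth, seed = spec$seed)
  expr <- gen_expression(cat1$truth, replicates = spec$replicates,
                         noise_cv = spec$noise_cv, seed = spec$seed + 3L)
  cat1$truth$enriched_terms <- ann$enriched_terms
  structure(list(records = cat1$records, taxa = cat1$taxa,
                 terms = ann$terms, panels = cat1$panels,
                 expression = expr, truth = cat1$truth, spec = spec),
            class = "atlas_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits the plain-text formats consumed by the pipeline stages and external
#' tools: protein FASTA, expression TSV (`gene_id` then `M1_1 ... carcass_r`
#' columns), taxon- and term-annotation TSVs, one panel FASTA per family, and
#' a truth TSV.
#'
#' @param sim an `atlas_sim` from [simulate_atlas()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the named vector of files written.
#' @export
write_synthetic <- function(sim, outdir) {
  stopifnot(inherits(sim, "atlas_sim"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()

  fa <- file.path(outdir, "unigenes.fa")
  write_fasta(stats::setNames(sim$records$sequence, sim$records$accession), fa)
  paths["fasta"] <- fa

  expr <- file.path(outdir, "expression.tsv")
  write_expression_tsv(sim$expression, expr)
  paths["expression"] <- expr

  taxa <- file.path(outdir, "taxa.tsv")
  utils::write.table(sim$taxa, taxa, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["taxa"] <- taxa

  terms <- file.path(outdir, "terms.tsv")
  utils::write.table(sim$terms, terms, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["terms"] <- terms

  pdir <- file.path(outdir, "panels")
  dir.create(pdir, showWarnings = FALSE)
  for (nm in names(sim$panels)) {
    p <- sim$panels[[nm]]
    f <- file.path(pdir, paste0(nm, ".fa"))
    write_fasta(unlist(unname(p$members_by_species)), f)
    paths[paste0("panel_", nm)] <- f
  }

  tr <- data.frame(gene_id = names(sim$truth$archetype),
                   archetype = unname(sim$truth$archetype),
                   contaminant = unname(sim$truth$contaminant),
                   contained = unname(sim$truth$contained),
                   family = unname(sim$truth$family),
                   stringsAsFactors = FALSE)
  truth <- file.path(outdir, "truth.tsv")
  utils::write.table(tr, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["truth"] <- truth

  invisible(paths)
}
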