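test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(n_genes = -5), "n_genes")
  expect_error(synthetic_spec(contaminant_frac = 1.5), "contaminant_frac")
  expect_error(synthetic_spec(noise_cv = -1), "noise_cv")
  w <- stats::setNames(c(rep(0.2, 8), 0), ARCHETYPES)
  expect_error(synthetic_spec(archetype_weights = w), "archetype_weights")
})

test_that("generation is byte-deterministic under a fixed seed", {
  spec <- synthetic_spec(n_genes = 120, seed = 9)
  s1 <- simulate_atlas(spec)
  s2 <- simulate_atlas(spec)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$expression, s2$expression)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(stats::setNames(s1$records$sequence, s1$records$accession), f1)
  write_fasta(stats::setNames(s2$records$sequence, s2$records$accession), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("contaminant flagging follows the requested fraction", {
  spec0 <- synthetic_spec(n_genes = 200, contaminant_frac = 0, seed = 3)
  cat0 <- gen_unigene_catalog(spec0)
  expect_equal(sum(cat0$truth$contaminant), 0)
  expect_false(any(cat0$taxa$taxon_group %in% c("bacteria", "plants") &
                     cat0$taxa$e_value < 1e-05))

  spec1 <- synthetic_spec(n_genes = 1000, contaminant_frac = 0.1, seed = 3)
  cat1 <- gen_unigene_catalog(spec1)
  # binomial 99% interval for Binom(1000, 0.1), computed by base qbinom
  ci <- stats::qbinom(c(0.005, 0.995), 1000, 0.1)
  expect_gte(sum(cat1$truth$contaminant), ci[1])
  expect_lte(sum(cat1$truth$contaminant), ci[2])
  # every contaminant carries a sub-threshold excluded-taxon annotation
  flagged <- names(cat1$truth$contaminant)[cat1$truth$contaminant]
  strong <- cat1$taxa[cat1$taxa$e_value < 1e-05 &
                        cat1$taxa$taxon_group %in% c("bacteria", "plants"), ]
  expect_true(all(flagged %in% strong$gene_id))
})

test_that("catalog structure: Trinity IDs parse, isoforms have distinct lengths, containment is planted", {
  sim <- small_sim(300, 5)
  parsed <- parse_trinity_id(sim$records$accession)
  expect_false(anyNA(parsed$gene_id))
  by_gene <- split(sim$records$length, sim$records$gene_id)
  multi <- by_gene[lengths(by_gene) > 1]
  expect_true(length(multi) > 0)
  expect_true(all(vapply(multi, function(l) !anyDuplicated(l), logical(1))))
  # planted contained genes really are substrings of some other record
  seqs <- sim_gene_seqs(sim)
  contained <- names(sim$truth$contained)[sim$truth$contained]
  expect_true(length(contained) > 0)
  for (g in contained[1:3]) {
    others <- seqs[setdiff(names(seqs), g)]
    expect_true(any(vapply(others, function(h)
      grepl(seqs[[g]], h, fixed = TRUE), logical(1))))
  }
})

test_that("expression honors archetypes: zero noise reproduces means, peaks are where planted", {
  sim <- small_sim(300, 5)
  ex0 <- gen_expression(sim$truth, replicates = 3, noise_cv = 0, seed = 1)
  tis <- sub("_[0-9]+$", "", colnames(ex0))
  for (t in MIDGUT_TISSUES) {
    cols <- which(tis == t)
    expect_true(all(ex0[, cols[1]] == ex0[, cols[2]]))
  }
  means <- average_replicates(ex0, MIDGUT_TISSUES)
  m1_genes <- names(sim$truth$archetype)[sim$truth$archetype == "M1"]
  expect_true(all(means[m1_genes, "M1"] > means[m1_genes, "M2"]))
  expect_true(all(means[m1_genes, "M1"] > means[m1_genes, "M3"]))
  expect_true(all(means[m1_genes, "M1"] > means[m1_genes, "M4"]))
  inc <- names(sim$truth$archetype)[sim$truth$archetype == "increasing"]
  expect_true(all(means[inc, "M1"] < means[inc, "M2"] &
                    means[inc, "M2"] < means[inc, "M3"] &
                    means[inc, "M3"] < means[inc, "M4"]))
  expect_true(all(ex0 >= 0))
  expect_error(gen_expression(sim$truth, replicates = 1), "replicates")
  bad <- sim$truth; bad$archetype[1] <- "no_such_pattern"
  expect_error(gen_expression(bad, replicates = 2), "no_such_pattern")
})

test_that("replicate noise has roughly the requested CV", {
  sim <- small_sim(300, 5)
  ex <- gen_expression(sim$truth, replicates = 200, noise_cv = 0.2, seed = 2)
  flat <- names(sim$truth$archetype)[sim$truth$archetype == "flat"][1:20]
  cols <- grepl("^M1_", colnames(ex))
  cv <- apply(ex[flat, cols], 1, function(v) stats::sd(v) / mean(v))
  expect_true(all(abs(cv - 0.2) < 0.06))
})

test_that("archetype proportions converge to the weights", {
  spec <- synthetic_spec(n_genes = 5000, seed = 21)
  cat5k <- gen_unigene_catalog(spec)
  clean <- !cat5k$truth$contaminant  # contaminants get biased archetypes
  obs <- table(factor(cat5k$truth$archetype[clean], levels = ARCHETYPES))
  p <- stats::chisq.test(obs, p = spec$archetype_weights)$p.value
  expect_gt(p, 0.01)
})

test_that("planted family members carry their templates; decoys carry neither", {
  sim <- small_sim(300, 5)
  seqs <- sim_gene_seqs(sim)
  fam <- sim$truth$family
  cyp <- names(fam)[!is.na(fam) & fam == "CYP"]
  expect_true(all(grepl("F..G.[RH].C.G", seqs[cyp])))
  sp <- names(fam)[!is.na(fam) & fam == "SP"]
  expect_true(all(vapply(seqs[sp], count_tm, integer(1)) >= 3))
  aaap <- names(fam)[!is.na(fam) & fam == "AAAP"]
  expect_true(all(vapply(seqs[aaap], count_tm, integer(1)) >= 3))
  decoys <- names(fam)[is.na(fam)]
  expect_false(any(grepl("F..G.[RH].C.G", seqs[decoys])))
  # panel members must carry the template too and respect the length range
  for (p in sim$panels) {
    lens <- nchar(p$members)
    expect_true(all(lens >= p$min_len & lens <= p$max_len))
  }
  expect_true(all(vapply(sim$panels$SP$members, count_tm, integer(1)) >= 3))
})
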