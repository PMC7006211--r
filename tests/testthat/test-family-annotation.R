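mini_panels <- function() {
  sim <- small_sim(300, 5)
  sim$panels
}

test_that("family panel statistics use the sample SD over combined members", {
  p <- family_panel("TEST", list(
    Hsap = c(h1 = paste(rep("A", 400), collapse = "")),
    Dmel = c(d1 = paste(rep("A", 450), collapse = ""),
             d2 = paste(rep("A", 500), collapse = ""))))
  expect_equal(p$min_len, 400)
  expect_equal(p$max_len, 500)
  expect_equal(p$sd_len, 50)  # sample sd of {400, 450, 500}
  # length filter window [350, 550], bounds inclusive
  expect_false(length_filter(340, p))
  expect_true(length_filter(360, p))
  expect_true(length_filter(350, p))
  expect_true(length_filter(550, p))
  expect_false(length_filter(551, p))
  # single member: sd 0
  p1 <- family_panel("ONE", list(Hsap = c(h = "AAAA")))
  expect_equal(p1$sd_len, 0)
  expect_error(family_panel("EMPTY", list(Hsap = character(0))), "no members")
})

test_that("classification applies the top-hit, vote and identity rules", {
  panels <- list(
    AAAP = family_panel("AAAP", list(Hsap = stats::setNames(
      rep("A", 6), paste0("aaap", 1:6)))),
    APC = family_panel("APC", list(Hsap = stats::setNames(
      rep("A", 6), paste0("apc", 1:6)))),
    TRI = family_panel("TRI", list(Hsap = stats::setNames(
      rep("A", 3), paste0("tri", 1:3)))))
  hit <- function(subject, e, id) data.frame(
    query = "cand", subject = subject, identity = id, align_len = 100,
    q_start = 1, q_end = 100, s_start = 1, s_end = 100,
    e_value = e, bit_score = -log10(e), stringsAsFactors = FALSE)

  # all top 5 in AAAP, 35% identity -> assigned
  h1 <- do.call(rbind, lapply(1:5, function(i) hit(paste0("aaap", i), 10^(-20 + i), 35)))
  expect_equal(classify_family(h1, panels)$family, "AAAP")

  # top hit APC but only 3 of 5 in APC (|APC| >= 5) -> no call
  h2 <- rbind(hit("apc1", 1e-30, 40), hit("aaap1", 1e-28, 40),
              hit("apc2", 1e-26, 40), hit("aaap2", 1e-24, 40),
              hit("apc3", 1e-22, 40))
  expect_true(is.na(classify_family(h2, panels)$family))

  # small family (3 members), all in top 5, 25% identity -> assigned
  h3 <- rbind(hit("tri1", 1e-30, 25), hit("apc1", 1e-28, 30),
              hit("tri2", 1e-26, 25), hit("tri3", 1e-24, 25),
              hit("aaap1", 1e-22, 30))
  expect_equal(classify_family(h3, panels)$family, "TRI")

  # identity below 20% fails rule iii
  h4 <- do.call(rbind, lapply(1:5, function(i) hit(paste0("aaap", i), 10^(-20 + i), 15)))
  expect_true(is.na(classify_family(h4, panels)$family))

  # no hits -> no call
  expect_true(is.na(classify_family(NULL, panels)$family))
})

test_that("P450 candidate filters reject short, weak, low-coverage and motif-less genes", {
  sim <- small_sim(300, 5)
  seqs <- sim_gene_seqs(sim)
  curated <- sim$panels$CYP$members
  calls <- p450_candidates(seqs, curated)
  planted <- names(sim$truth$family)[!is.na(sim$truth$family) &
                                       sim$truth$family == "CYP"]
  expect_setequal(calls$gene_id, planted)
  expect_true(all(calls$len_ok & calls$reciprocal_ok & calls$domain_ok))
  # truncating a planted member below 150 residues removes it
  short <- seqs
  short[planted[1]] <- substr(short[planted[1]], 1, 120)
  calls2 <- p450_candidates(short, curated)
  expect_false(planted[1] %in% calls2$gene_id)
  # stripping the motif removes it too
  nomotif <- seqs
  nomotif[planted[2]] <- gsub("F(..G.[RH].C.G)", "D\\1", nomotif[planted[2]])
  calls3 <- p450_candidates(nomotif, curated)
  expect_false(planted[2] %in% calls3$gene_id)
  # an external domain table overrides the motif check
  calls4 <- p450_candidates(nomotif, curated, domain_genes = planted)
  expect_true(planted[2] %in% calls4$gene_id)
})

test_that("fragment merging joins on exact overlap and reaches a fixed point", {
  fr <- c(a = "AAAACCCC", b = "CCCCGGGG")
  m <- merge_fragments(fr, min_overlap = 4)
  expect_equal(as.character(m), "AAAACCCCGGGG")
  expect_equal(nchar(m[[1]]), 8 + 8 - 4)
  expect_equal(names(m), "a+b")
  # disjoint fragments stay unmerged
  d <- merge_fragments(c(x = "AAAA", y = "GGGG"), min_overlap = 3)
  expect_length(d, 2)
  # identical candidates collapse to one record
  expect_length(merge_fragments(c(p = "MMMM", q = "MMMM"), min_overlap = 3), 1)
  # three-way chain resolves regardless of input order
  ch <- c(z = "GGGGTTTT", a = "AAAACCCC", m = "CCCCGGGG")
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    got <- merge_fragments(ch[perm], min_overlap = 4)
    expect_equal(as.character(got), "AAAACCCCGGGGTTTT")
  }
  # conflicting joins: two fragments compete for the same prefix -> no join
  cf <- c(a = "AAAACCCC", b = "TTTTCCCC", s = "CCCCGGGG")
  got <- merge_fragments(cf, min_overlap = 4)
  expect_length(got, 3)
  expect_equal(attr(got, "conflicts"), "s")
  # idempotence
  again <- merge_fragments(got, min_overlap = 4)
  expect_equal(sort(unname(again)), sort(unname(got)))
})

test_that("iterative annotation recovers planted families and never revokes calls", {
  sim <- small_sim(300, 5)
  seqs <- sim_gene_seqs(sim)
  calls <- iterative_annotate(seqs, sim$panels)
  truth <- sim$truth$family
  planted <- names(truth)[!is.na(truth)]
  tp <- sum(calls$gene_id %in% planted &
              calls$family == truth[calls$gene_id])
  expect_gte(tp / nrow(calls), 0.95)   # precision
  expect_gte(tp / length(planted), 0.95)  # recall
  # second pass over already-annotated genes adds nothing new
  calls2 <- iterative_annotate(seqs, sim$panels)
  expect_equal(calls2, calls)
  # transporter calls all satisfy the TM minimum
  tr <- calls[calls$family != "CYP", ]
  expect_true(all(tr$tm_count >= 3))
})

test_that("family expression summaries average members and count strict thresholds", {
  calls <- data.frame(gene_id = c("g1", "g2", "g3"),
                      family = c("SP", "SP", "NSS"))
  means <- rbind(g1 = c(10, 1, 2, 10, 0), g2 = c(90, 3, 4, 50, 0),
                 g3 = c(0.5, 0.5, 0.5, 0.5, 0.5))
  colnames(means) <- MIDGUT_TISSUES
  s <- summarize_family_expression(calls, means)
  sp_m1 <- s[s$family == "SP" & s$tissue == "M1", ]
  expect_equal(sp_m1$mean_tpm, 50)        # mean of 10 and 90
  expect_equal(sp_m1$n_over_50, 1)        # 90 only
  expect_equal(sp_m1$n_over_5, 2)
  # threshold is strict: a member at exactly 50 is not counted
  sp_m4 <- s[s$family == "SP" & s$tissue == "M4", ]
  expect_equal(sp_m4$n_over_50, 0)        # values 10 and 50
  # genes at <= 1 TPM everywhere are excluded first; NSS becomes empty
  expect_equal(attr(s, "empty_families"), "NSS")
  expect_true(all(s$mean_tpm[s$family == "NSS"] == 0))
  # single-member family: average equals the member
  one <- summarize_family_expression(
    data.frame(gene_id = "g1", family = "SP"), means)
  expect_equal(one$mean_tpm[one$tissue == "M1"], 10)
})
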