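test_that("consensus CAZyme calls require the two-of-three tool vote", {
  one_tool <- hit_row("pA", "hmmer", "GH16")
  expect_equal(nrow(consensus_cazyme(one_tool)), 0)

  all_three <- rbind(hit_row("pA", "hmmer", "GH16"),
                     hit_row("pA", "diamond", "GH16"),
                     hit_row("pA", "dbcan_sub", "GH16_3"))
  call <- consensus_cazyme(all_three)
  expect_equal(call$family, "GH16")
  expect_equal(call$subfamily, "GH16_3")
  expect_equal(call$support, 3L)

  # votes are counted per family: GH16 x2 + GH17 x1 -> one GH16 call
  split_vote <- rbind(hit_row("pB", "hmmer", "GH16"),
                      hit_row("pB", "diamond", "GH16"),
                      hit_row("pB", "dbcan_sub", "GH17_1"))
  call <- consensus_cazyme(split_vote)
  expect_equal(call$family, "GH16")
  expect_equal(call$support, 2L)

  expect_error(consensus_cazyme(all_three, min_tools = 4), "config error")
})

test_that("consensus calls are idempotent, order-invariant and capped at the tool-set size", {
  set.seed(7)
  hits <- do.call(rbind, lapply(1:20, function(i) {
    fam <- sample(c("GH16", "GH3", "GT2", "CE1"), 1)
    tools <- sample(c("hmmer", "diamond", "dbcan_sub"), sample(1:3, 1))
    do.call(rbind, lapply(tools, function(tl) hit_row(paste0("p", i), tl, fam)))
  }))
  a <- consensus_cazyme(hits)
  b <- consensus_cazyme(hits[sample(nrow(hits)), ])
  c2 <- consensus_cazyme(rbind(hits, hits))  # duplicated evidence
  expect_equal(a, b)
  expect_equal(a, c2)
  expect_true(all(a$support <= 3))
  # per-family oracle: distinct-tool vote count
  key <- paste(hits$protein_id, sub("_.*", "", hits$label))
  votes <- tapply(hits$tool, key, function(t) length(unique(t)))
  expect_equal(nrow(a), sum(votes >= 2))
})

test_that("SusC evidence classes split on specific versus superfamily hits", {
  hits <- rbind(hit_row("sc1", "cdd", "TIGR04056", "specific"),
                hit_row("sc1", "cdd", "TIGR04056", "superfamily"),
                hit_row("sc2", "cdd", "TIGR04056", "superfamily"),
                hit_row("sd1", "cdd", "SusD"),
                hit_row("px", "hmmer", "GH16"))
  sus <- classify_sus(hits)
  expect_equal(sus$class[sus$protein_id == "sc1"], "susC_specific")
  expect_equal(sus$class[sus$protein_id == "sc2"], "susC_superfamily")
  expect_equal(sus$class[sus$protein_id == "sd1"], "susD")
  expect_false("px" %in% sus$protein_id)
  # no protein receives two classes
  expect_false(any(duplicated(sus$protein_id)))
})

test_that("proteins with both SusC and SusD evidence are excluded as conflicts", {
  hits <- rbind(hit_row("amb", "cdd", "TIGR04056", "specific"),
                hit_row("amb", "cdd", "SusD"))
  expect_warning(sus <- classify_sus(hits), "both SusC and SusD")
  expect_equal(nrow(sus), 0)
  expect_equal(attr(sus, "conflicts"), "amb")
})

test_that("SusC/D pairing follows the tandem geometry", {
  sus_for <- function(susc, susd) {
    data.frame(protein_id = c(susc, susd),
               class = c(rep("susC_specific", length(susc)),
                         rep("susD", length(susd))))
  }
  g <- make_toy_genome(10)
  # lone susC -> no pair
  expect_equal(nrow(detect_suscd_pairs(g, sus_for("p4", character(0)))), 0)
  # susC rank 3 (+), susD rank 4 (+) -> one pair
  pairs <- detect_suscd_pairs(g, sus_for("p4", "p5"))
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$susC_gene, "g4")
  expect_equal(pairs$susD_gene, "g5")
  # susD three ranks downstream -> no pair under default geometry
  expect_equal(nrow(detect_suscd_pairs(g, sus_for("p4", "p7"))), 0)
  # ... unless intervening ORFs are allowed
  expect_equal(nrow(detect_suscd_pairs(g, sus_for("p4", "p7"),
                                       max_intervening = 2)), 1)
  # minus-strand susC reads right-to-left: susD must sit at rank - 1
  gm <- make_toy_genome(10, strands = rep("-", 10))
  expect_equal(nrow(detect_suscd_pairs(gm, sus_for("p4", "p5"))), 0)
  pm <- detect_suscd_pairs(gm, sus_for("p4", "p3"))
  expect_equal(pm$susD_gene, "g3")
  # opposite strands break the tandem unless strand-agnostic
  gx <- make_toy_genome(10, strands = c(rep("+", 4), "-", rep("+", 5)))
  expect_equal(nrow(detect_suscd_pairs(gx, sus_for("p4", "p5"))), 0)
  expect_equal(nrow(detect_suscd_pairs(gx, sus_for("p4", "p5"),
                                       same_strand = FALSE)), 1)
})

test_that("pairing agrees with an exhaustive pair scan and uses each gene once", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- 30
    strands <- sample(c("+", "-"), n, replace = TRUE)
    g <- make_toy_genome(n, strands = strands)
    susc <- paste0("g", sample(n, 5))
    susd <- paste0("g", sample(setdiff(seq_len(n), as.integer(sub("g", "", susc))), 5))
    sus <- data.frame(protein_id = sub("g", "p", c(susc, susd)),
                      class = c(rep("susC_specific", 5), rep("susD", 5)))
    got <- detect_suscd_pairs(g, sus)
    want <- oracle_suscd_pairs(gene_table(g), susc, susd)
    expect_equal(nrow(got), length(want))
    if (length(want) > 0) {
      expect_equal(got$susC_gene, vapply(want, `[[`, "", "susC"))
      expect_equal(got$susD_gene, vapply(want, `[[`, "", "susD"))
    }
    expect_false(any(duplicated(c(got$susC_gene, got$susD_gene))))
  }
})

test_that("motif scanning finds the conserved GH16 finger motifs exactly", {
  pad1 <- "MKTAYIAKQR"; pad2 <- "LDNGAEVKQH"
  seq1 <- paste0(pad1, gh16_motifs$finger3_trp, pad2)
  hit <- scan_motif(seq1, gh16_motifs$finger3_trp)
  expect_equal(hit$start, nchar(pad1) + 1L)
  expect_equal(hit$match, gh16_motifs$finger3_trp)
  seq2 <- paste0(pad2, gh16_motifs$finger1_gal, pad1)
  expect_equal(scan_motif(seq2, gh16_motifs$finger1_gal)$start,
               nchar(pad2) + 1L)
  # no match cases
  expect_equal(nrow(scan_motif("", "WPA")), 0)
  expect_equal(nrow(scan_motif("WP", "WPA")), 0)
  expect_equal(nrow(scan_motif(seq1, gh16_motifs$finger1_gal)), 0)
})

test_that("motif scanning tolerates bounded mismatches but never matches X", {
  mut <- sub("ALGAN", "ALGSN", gh16_motifs$finger3_trp)  # one substitution
  seqm <- paste0("AAAA", mut, "AAAA")
  expect_equal(nrow(scan_motif(seqm, gh16_motifs$finger3_trp, 0)), 0)
  expect_equal(scan_motif(seqm, gh16_motifs$finger3_trp, 1)$start, 5L)
  # X in the sequence counts as mismatch even against an identical motif char
  expect_equal(nrow(scan_motif("AWXA", "WXA", 0)), 0)
  expect_equal(scan_motif("AWXA", "WXA", 1)$start, 2L)
})

test_that("mismatch scanning agrees with the naive offset loop on random sequences", {
  set.seed(11)
  for (i in 1:40) {
    s <- random_protein(60)
    motif <- random_protein(sample(3:8, 1),
                            alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    k <- sample(0:2, 1)
    expect_equal(scan_motif(s, motif, k)$start, oracle_motif_search(s, motif, k))
  }
})

gh16_domains <- function(drop = character(0)) {
  d <- data.frame(
    name = c("signal_peptide", "lipid_attachment", "laminarin_binding",
             "PKD", "GH16_cat_N", "inserted_DUF", "GH16_cat_C", "WPA_site"),
    start = c(1, 1, 6, 48, 320, 525, 615, 640),
    end = c(20, 18, 294, 109, 520, 610, 690, 642))
  d[!d$name %in% drop, ]
}

test_that("the canonical large-laminarinase architecture is recognised", {
  arch <- domain_architecture("lamA", 700, gh16_domains())
  res <- classify_gh16_architecture(arch)
  expect_equal(res$class, "canonical_large_laminarinase")
  expect_length(res$flags, 0)
  # PKD absent -> non-canonical
  res2 <- classify_gh16_architecture(
    domain_architecture("lamB", 700, gh16_domains(drop = "PKD")))
  expect_equal(res2$class, "non_canonical")
  expect_equal(res2$missing, "PKD")
  # out-of-window length flags but does not demote
  res3 <- classify_gh16_architecture(
    domain_architecture("lamC", 720,
                        within(gh16_domains(), end[name == "GH16_cat_C"] <- 700)))
  expect_equal(res3$class, "canonical_large_laminarinase")
  expect_true("length_out_of_window" %in% res3$flags)
})

test_that("architecture validation rejects bad spans and derives the WPA site", {
  bad <- gh16_domains()
  bad$end[bad$name == "PKD"] <- 400  # overlaps GH16_cat_N
  expect_error(classify_gh16_architecture(domain_architecture("x", 700, bad)),
               "overlapping mandatory")
  oob <- gh16_domains()
  oob$end[oob$name == "GH16_cat_C"] <- 800
  expect_error(classify_gh16_architecture(domain_architecture("x", 700, oob)),
               "outside")
  # WPA site derived from the sequence within the catalytic span
  seqlam <- paste(rep("A", 700), collapse = "")
  substr(seqlam, 640, 642) <- "WPA"
  arch <- domain_architecture("lamD", 700, gh16_domains(drop = "WPA_site"),
                              sequence = seqlam)
  expect_true("WPA_site" %in% arch$domains$name)
  expect_equal(classify_gh16_architecture(arch)$class,
               "canonical_large_laminarinase")
})

test_that("architecture classification reproduces the rule over the domain-presence grid", {
  required <- c("signal_peptide", "PKD", "laminarin_binding", "GH16_cat_N",
                "inserted_DUF", "GH16_cat_C", "WPA_site")
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(required)))
  names(grid) <- required
  for (i in seq_len(nrow(grid))) {
    present <- required[unlist(grid[i, ])]
    arch <- domain_architecture("p", 700,
                                gh16_domains(drop = setdiff(required, present)))
    got <- classify_gh16_architecture(arch)$class
    expect_equal(got, oracle_gh16_rule(arch$domains$name))
  }
})
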