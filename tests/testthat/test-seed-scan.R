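# toy miR: seed6 = GCUAGC (its own reverse complement), position 8 = G so
# the m8-pairing UTR base is C, position 1 = A
toy_mir <- mature_mir("toy-miR", "AGCUAGCGUUUU")

test_that("constructed matches are found with the right type and span", {
  # 6mer: non-A 3' flank, non-C 5' flank
  hits <- find_seed_sites(toy_mir, utr_seq("u1", "AAAGCUAGCGAA"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 4L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$site_type, "6mer")
  expect_equal(hits$target_seq, "GCUAGC")

  # an A immediately 3' of the core upgrades the locus to 7mer-A1
  a1 <- find_seed_sites(toy_mir, utr_seq("u2", "AAAGCUAGCAAA"))
  expect_equal(a1$site_type, "7mer-A1")
  expect_equal(c(a1$start, a1$end), c(4L, 10L))

  # a C immediately 5' (pairs miR position 8 = G) makes a 7mer-m8
  m8 <- find_seed_sites(toy_mir, utr_seq("u3", "AACGCUAGCGAA"))
  expect_equal(m8$site_type, "7mer-m8")
  expect_equal(c(m8$start, m8$end), c(3L, 9L))

  # both context features give the 8mer
  full <- find_seed_sites(toy_mir, utr_seq("u4", "AACGCUAGCAAA"))
  expect_equal(full$site_type, "8mer")
  expect_equal(c(full$start, full$end), c(3L, 10L))
})

test_that("degenerate inputs are handled per contract", {
  expect_equal(nrow(find_seed_sites(toy_mir, utr_seq("u", "ACG"))), 0L)
  expect_error(mature_mir("tiny", "ACGU"), "at least 8")
  # N never matches
  expect_equal(nrow(find_seed_sites(toy_mir, utr_seq("u", "AAAGCUNGCGAA"))),
               0L)
})

test_that("DNA-alphabet UTRs scan identically to their RNA normalisation", {
  set.seed(81)
  for (i in 1:20) {
    rna <- random_utr_string(200)
    dna <- chartr("U", "T", rna)
    a <- find_seed_sites(toy_mir, utr_seq("u", rna))
    b <- find_seed_sites(toy_mir, utr_seq("u", dna))
    expect_equal(a[c("start", "end", "site_type")],
                 b[c("start", "end", "site_type")])
  }
})

test_that("scanner equals the brute-force per-offset oracle on random pairs", {
  set.seed(82)
  for (i in 1:60) {
    mseq <- random_mir_seq(sample(18:24, 1))
    useq <- random_utr_string(sample(c(60, 150, 400), 1))
    mir <- mature_mir("m", mseq)
    got <- find_seed_sites(mir, utr_seq("u", useq))
    exp <- oracle_scan(mseq, useq)
    expect_equal(got[c("start", "end", "site_type")], exp,
                 ignore_attr = TRUE)
    # coordinate round-trip: the span reproduces target_seq
    if (nrow(got))
      expect_identical(substring(useq, got$start, got$end), got$target_seq)
  }
})

test_that("no reported 6mer shares a register with a reportable stronger type", {
  set.seed(83)
  n_hits <- 0L
  for (i in 1:5) {
    mir <- mature_mir("m", random_mir_seq())
    hits <- find_seed_sites(mir, utr_seq("u", random_utr_string(20000)))
    n_hits <- n_hits + nrow(hits)
    core_start <- ifelse(hits$site_type %in% c("7mer-m8", "8mer"),
                         hits$start + 1L, hits$start)
    expect_false(any(duplicated(core_start)))
  }
  expect_gt(n_hits, 0L)  # the property was exercised on real matches
})

test_that("wt/variant comparison partitions sites and spots planted extras", {
  mirs <- list(toy_mir)
  wt <- utr_seq("wt", paste0(random_utr_string(0),
                             "CCGGUUAAGCUAGCGUUCCGGAAUUCCGG"))
  # identical sequence: everything shared
  cmp <- compare_wt_variant_sites(wt, utr_seq("var", wt$sequence), mirs)
  expect_equal(nrow(cmp$wt_only), 0L)
  expect_equal(nrow(cmp$variant_only), 0L)
  expect_equal(nrow(cmp$shared), nrow(scan_utrs(mirs, wt)))

  # appending an extra site yields exactly that site in variant_only
  extra <- paste0(wt$sequence, "UUCUUGCUAGCGUU")
  cmp2 <- compare_wt_variant_sites(wt, utr_seq("var", extra), mirs)
  expect_equal(nrow(cmp2$wt_only), 0L)
  expect_equal(nrow(cmp2$variant_only), 1L)
  expect_equal(nrow(cmp2$shared), nrow(scan_utrs(mirs, wt)))

  set.seed(84)
  mirs2 <- lapply(1:2, function(i) mature_mir(paste0("m", i),
                                              random_mir_seq()))
  for (rep in 1:25) {
    # simulated wt/variant pair: variant = wt plus a 3' extension that
    # carries one planted extra site
    base_cfg <- utr_sim_config(
      length = 300,
      planted_sites = data.frame(mir_name = "m1", site_type = "7mer-m8",
                                 start = sample(50:200, 1)),
      rng_seed = rep)
    wt_sim <- simulate_utr(base_cfg, mirs2, id = "wt")
    ext_cfg <- utr_sim_config(
      length = 80,
      planted_sites = data.frame(mir_name = "m2", site_type = "8mer",
                                 start = 30L),
      rng_seed = rep + 1000L)
    ext <- simulate_utr(ext_cfg, mirs2, id = "ext")
    var <- utr_seq("var", paste0(wt_sim$utr$sequence, ext$utr$sequence))
    cmp <- compare_wt_variant_sites(wt_sim$utr, var, mirs2)
    n_wt <- nrow(scan_utrs(mirs2, wt_sim$utr))
    n_var <- nrow(scan_utrs(mirs2, var))
    # partition covers all sites of both UTRs
    expect_equal(2 * nrow(cmp$shared) + nrow(cmp$wt_only) +
                   nrow(cmp$variant_only), n_wt + n_var)
    # the planted extension site is variant-specific
    expect_true(any(cmp$variant_only$mir_name == "m2" &
                      cmp$variant_only$site_type == "8mer"))
  }
})

test_that("seed-site mutagenesis abolishes the targeted site and nothing else", {
  set.seed(85)
  mirs <- lapply(1:2, function(i) mature_mir(paste0("m", i),
                                             random_mir_seq()))
  for (rep in 1:30) {
    ty <- sample(c("6mer", "7mer-A1", "7mer-m8", "8mer"), 1)
    cfg <- utr_sim_config(
      length = 240,
      planted_sites = data.frame(
        mir_name = c("m1", "m1"), site_type = c(ty, "6mer"),
        start = c(60L, 160L)),
      rng_seed = rep)
    sim <- simulate_utr(cfg, mirs, id = "u")
    site <- sim$truth[sim$truth$start == 60L, ]
    mut <- mutate_seed_site(sim$utr, site, mirs[[1]], n_mut = 3,
                            rng_seed = rep)
    rescanned <- find_seed_sites(mirs[[1]], mut)
    # brute-force oracle confirms no site of any type overlaps the span
    orc <- oracle_scan(mirs[[1]]$sequence, mut$sequence)
    expect_false(any(orc$start <= site$end & orc$end >= site$start))
    expect_false(any(rescanned$start <= site$end &
                       rescanned$end >= site$start))
    # the untouched site is still there
    expect_true(any(rescanned$start == 160L))
    # exactly n_mut positions differ, all inside the seed-pairing span
    diff <- which(strsplit(sim$utr$sequence, "")[[1]] !=
                    strsplit(mut$sequence, "")[[1]])
    expect_equal(length(diff), 3L)
    expect_true(all(diff >= site$start & diff <= site$end))
  }
})

test_that("mutagenesis is reproducible under a fixed seed and validates inputs", {
  mirs <- list(toy_mir)
  cfg <- utr_sim_config(length = 120, planted_sites = data.frame(
    mir_name = "toy-miR", site_type = "8mer", start = 50L), rng_seed = 9)
  sim <- simulate_utr(cfg, mirs, id = "u")
  site <- sim$truth[1, ]
  m1 <- mutate_seed_site(sim$utr, site, toy_mir, n_mut = 3, rng_seed = 42)
  m2 <- mutate_seed_site(sim$utr, site, toy_mir, n_mut = 3, rng_seed = 42)
  expect_identical(m1$sequence, m2$sequence)
  expect_error(mutate_seed_site(sim$utr, site, toy_mir, n_mut = 20),
               "n_mut")
})

test_that("site conservation counts intact orthologous sites", {
  mirs <- list(toy_mir)
  utr <- "AACGCUAGCAAAUUCCGGAAUU"  # 8mer at 3-10
  site <- find_seed_sites(toy_mir, utr_seq("ref", utr))
  expect_equal(site$site_type, "8mer")

  aln_same <- stats::setNames(rep(utr, 5),
                              c("ref", paste0("sp", 1:4)))
  expect_equal(site_conservation(aln_same, site, toy_mir, ref = "ref"), 1.0)

  # every non-reference species carries a seed-disrupting substitution
  broken <- sub("GCUAGC", "GCAAGC", utr)
  aln_broken <- stats::setNames(c(utr, rep(broken, 4)),
                                c("ref", paste0("sp", 1:4)))
  expect_equal(site_conservation(aln_broken, site, toy_mir, ref = "ref"),
               0.2)

  # a species whose site falls into gaps is not intact
  gapped <- sub("GCUAGCA", "-------", utr)
  aln_gap <- stats::setNames(c(utr, gapped), c("ref", "sp1"))
  expect_equal(site_conservation(aln_gap, site, toy_mir, ref = "ref"), 0.5)
})

test_that("conservation equals a per-species rescanning oracle on random alignments", {
  set.seed(86)
  for (rep in 1:20) {
    mir <- mature_mir("m", random_mir_seq())
    cfg <- utr_sim_config(length = 80, planted_sites = data.frame(
      mir_name = "m", site_type = "7mer-m8", start = 35L), rng_seed = rep)
    ref_sim <- simulate_utr(cfg, list(mir), id = "ref")
    site <- ref_sim$truth[1, ]
    ref <- ref_sim$utr$sequence
    n_sp <- 4
    seqs <- c(ref = ref)
    intact_truth <- TRUE  # reference
    for (s in 1:n_sp) {
      sp <- strsplit(ref, "")[[1]]
      disrupted <- stats::runif(1) < 0.5
      if (disrupted) {
        q <- sample(site$start:site$end, 1)
        sp[q] <- setdiff(c("A", "C", "G", "U"), sp[q])[1]
      }
      seqs[paste0("sp", s)] <- paste(sp, collapse = "")
      # oracle: rescan the full species sequence at the site span
      hits <- oracle_scan(mir$sequence, seqs[paste0("sp", s)])
      rank <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
      ok <- any(hits$start <= site$start & hits$end >= site$end &
                  rank[hits$site_type] >= rank[[site$site_type]])
      intact_truth <- c(intact_truth, ok)
    }
    expect_equal(site_conservation(seqs, site, mir, ref = "ref"),
                 mean(intact_truth))
  }
})
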