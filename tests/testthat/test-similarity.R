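test_that("translation picks frames and keeps internal stops", {
  expect_equal(as.character(translate_variant("ATGGCT", frame = 0)), "MA")
  # 5-nt input in frame 2 leaves one codon
  expect_equal(nchar(translate_variant("GGATG", frame = 2)), 1L)
  expect_error(translate_variant("AT", frame = 0), "too short")

  # auto-frame: encode an ORF in frame 1; frames 0/2 hit stops
  orf <- paste0("T", rev_translate("MKLVDEWQRTSAGH"))
  tr <- translate_variant(orf, frame = "auto")
  expect_equal(attr(tr, "frame"), 1L)
  expect_equal(as.character(tr), "MKLVDEWQRTSAGH")
})

test_that("local alignment reports identity, coverage and interval", {
  set.seed(171)
  q <- "MKLVDEWQRTSAGHLPYV"
  target <- paste0("AAAA", q, "GGGG")
  h <- align_identity(q, target)
  expect_equal(h$identity, 1.0)
  expect_equal(h$query_coverage, 1.0)
  expect_equal(substr(target, h$target_start + 1, h$target_end), q)

  # a hit covering half the query fails the 80% coverage gate
  half_target <- paste0("WWWW", substr(q, 1, 9))
  expect_null(align_identity(q, half_target, min_cov = 0.80))
  expect_false(is.null(align_identity(q, half_target, min_cov = 0.40)))
})

test_that("network-vs-reference scoring follows the matched-median rules", {
  # 4 domains all perfectly matching distinct reference proteins
  prots <- c("MKLVDEWQRTSAGHLPYVAA", "MHHQHSTVNNAGLLKWERPP",
             "MDDLKVVGGSSTTPPAAQQR", "MFFYYEEKKNNLLGGHHSSA")
  net <- make_network(vapply(prots, rev_translate, ""), id = "p")
  ref <- list(bgc_id = "refA",
              proteins = stats::setNames(
                paste0("XXXX", prots, "XXXX"), paste0("prot", 1:4)))
  res <- score_network_vs_reference(net, ref)
  expect_equal(res$matched_fraction, 1.0)
  expect_equal(res$score, 100)
  expect_equal(res$classification, "related")

  # the median convention: assigned {0.80, 0.90}, two unmatched zeros
  q1 <- strsplit("MKLVDEWQRTSAGHLPYVKEDQRSTVWYLEDHKNQRSTVW", "")[[1]]
  t80 <- q1; t80[c(5, 10, 15, 20, 25, 30, 33, 36)] <- "A"  # 8/40 swapped
  q2 <- strsplit("MHHQHSTVNNAGLLKWERPPMDDLKVVGGSSTTPPKKQQR", "")[[1]]
  t90 <- q2; t90[c(6, 13, 18, 24)] <- "G"                  # 4/40 swapped
  unrelA <- "MWWCCWWCCWWCCWWCCWWCCWWCCWWCCWWCCWWCCWWC"
  unrelB <- "MYYFFYYFFYYFFYYFFYYFFYYFFYYFFYYFFYYFFYYF"
  net2 <- make_network(vapply(c(paste(q1, collapse = ""),
                                paste(q2, collapse = ""),
                                unrelA, unrelB), rev_translate, ""),
                       id = "m")
  ref2 <- list(bgc_id = "refB",
               proteins = c(pA = paste(t80, collapse = ""),
                            pB = paste(t90, collapse = "")))
  res2 <- score_network_vs_reference(net2, ref2)
  expect_equal(res2$matched_fraction, 0.5)
  expect_equal(sort(res2$assigned), c(0, 0, 0.80, 0.90))
  expect_equal(res2$score, 40)  # median of {0, 0, 80, 90}
  expect_equal(res2$classification, "related")
  # the switchable convention excludes the zeros
  res2b <- score_network_vs_reference(net2, ref2,
                                      count_unmatched = FALSE)
  expect_equal(res2b$score, 85)

  # one match out of four falls below the 50% rule
  net3 <- make_network(vapply(c(prots[1], unrelA, unrelB,
                                "MAAGGAAGGAAGGAAGGAAG"),
                              rev_translate, ""), id = "u")
  res3 <- score_network_vs_reference(net3, ref)
  expect_equal(res3$matched_fraction, 0.25)
  expect_equal(res3$classification, "unrelated")
  expect_true(is.na(res3$score))
})

test_that("independent-position assignment equals exhaustive search", {
  set.seed(181)
  for (rep in 1:8) {
    n_nodes <- sample(2:5, 1)
    cand <- lapply(seq_len(n_nodes), function(i) {
      k <- sample(0:3, 1)
      if (k == 0)
        return(data.frame(target = character(), start = integer(),
                          end = integer(), identity = numeric()))
      start <- sample(0:60, k, replace = TRUE)
      data.frame(target = sample(c("p1", "p2"), k, TRUE),
                 start = start, end = start + sample(20:40, k, TRUE),
                 identity = round(runif(k, 0.3, 1), 3))
    })
    got <- conkatseq:::.best_assignment(cand)
    want <- oracle_assignment(cand)
    expect_equal(sum(got), sum(want), tolerance = 1e-12)
  }
})

test_that("novelty and cross-sample thresholds behave as step functions", {
  mk <- function(score, cls = "related")
    list(classification = cls, score = score)
  expect_equal(classify_novelty(list(mk(80))), "known")
  expect_equal(classify_novelty(list(mk(75))), "known")
  expect_equal(classify_novelty(list(mk(74.9))), "novel")
  expect_equal(classify_novelty(list(mk(70), mk(90))), "known")
  expect_equal(classify_novelty(list()), "novel")
  expect_equal(classify_novelty(list(mk(NA, "unrelated"))), "novel")
})

test_that("cross-network comparison applies the 50%/90% rule", {
  prots <- c("MKLVDEWQRTSAGHLPYVAA", "MHHQHSTVNNAGLLKWERPP",
             "MDDLKVVGGSSTTPPAAQQR", "MFFYYEEKKNNLLGGHHSSA")
  dna <- vapply(prots, rev_translate, "")
  net_a <- make_network(dna, id = "a")
  expect_true(compare_networks(net_a, net_a))

  # exactly 2 of 4 domains shared at 100%: boundary of the 50% rule
  unrel <- vapply(c("MWWCCWWCCWWCCWWCCWWC", "MYYFFYYFFYYFFYYFFYYF"),
                  rev_translate, "")
  net_b <- make_network(c(dna[1:2], unrel), id = "b")
  expect_true(compare_networks(net_a, net_b))

  # below 90% identity everywhere is unrelated even with full coverage
  prots85 <- vapply(prots, function(p) {
    ch <- strsplit(p, "")[[1]]
    ch[c(4, 9, 14)] <- "A"   # 17/20 = 85%
    paste(ch, collapse = "")
  }, "")
  net_c <- make_network(vapply(prots85, rev_translate, ""), id = "c")
  expect_false(compare_networks(net_a, net_c))
})

test_that("contig validation counts embedded vs absent domains", {
  set.seed(191)
  doms <- rand_dna(5, 60)
  spacer <- function() rand_dna(1, 40)
  contig <- paste0(spacer(), doms[1], spacer(), doms[2], spacer(),
                   doms[3], spacer(), doms[4], spacer(), doms[5],
                   spacer())
  net <- make_network(doms, id = "v")
  v <- validate_network_on_contig(net, contig)
  expect_equal(v$validated, 5L)
  expect_equal(v$false, 0L)

  # one domain absent from the contig
  net2 <- make_network(c(doms[1:4], rand_dna(1, 60)), id = "w")
  v2 <- validate_network_on_contig(net2, contig)
  expect_equal(v2$validated, 4L)
  expect_equal(v2$false, 1L)
  expect_equal(v2$validated + v2$false, 5L)

  # reverse-strand embedding still validates
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  expect_equal(validate_network_on_contig(net, rc)$validated, 5L)

  # ~5% mutated copy drops below the 93% identity threshold
  mut <- mutate_at(doms[1], seq(5, 60, by = 12))  # 55/60 = 0.917
  net3 <- make_network(mut, id = "x")
  v3 <- validate_network_on_contig(net3, contig, id_threshold = 0.93)
  expect_equal(v3$validated, 0L)
  v3b <- validate_network_on_contig(net3, contig, id_threshold = 0.90)
  expect_equal(v3b$validated, 1L)
})
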