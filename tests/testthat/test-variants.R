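test_that("dereplication counts unique sequences per subpool", {
  reads <- data.frame(
    subpool_id = c(rep("P", 7)),
    seq = c(rep("AAAA", 5), rep("CCCC", 2)))
  u <- dereplicate(reads)
  expect_equal(u$seq, c("AAAA", "CCCC"))
  expect_equal(u$count, c(5L, 2L))
  expect_equal(sum(u$count), nrow(reads))

  expect_equal(nrow(dereplicate(reads[0, ])), 0L)

  # same sequence in two subpools stays two records
  reads2 <- data.frame(subpool_id = c("P", "P", "Q"),
                       seq = rep("ACGT", 3))
  u2 <- dereplicate(reads2)
  expect_equal(nrow(u2), 2L)
  expect_equal(sort(u2$count), c(1L, 2L))
})

test_that("global identity counts gaps as alignment columns", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1.0)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  # terminal gap: best alignment has 3 matches over 4 columns
  expect_equal(pairwise_identity("ACGT", "ACG"), 0.75)
  expect_equal(pairwise_identity("ACG", "ACGT"), 0.75)
  # internal gap: ACGT vs AGT -> A-GT alignment, 3/4
  expect_equal(pairwise_identity("ACGT", "AGT"), 0.75)
  # symmetric
  set.seed(31)
  a <- rand_dna(1, 40); b <- mutate_at(rand_dna(1, 40), c(3, 17, 29))
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
})

test_that("greedy clustering joins by identity with abundance ordering", {
  set.seed(41)
  base <- rand_dna(1, 25)
  near <- mutate_at(base, 13L)        # 24/25 = 0.96 identity
  u <- data.frame(seq = c(base, near), subpool_id = c("P", "Q"),
                  count = c(10L, 3L))
  cl <- greedy_cluster(u, 0.95)
  expect_equal(nrow(cl$centroids), 1L)
  expect_equal(cl$centroids$centroid, base)   # higher abundance founds

  far <- mutate_at(base, c(3, 8, 13, 18, 23))  # 20/25 = 0.80
  cl2 <- greedy_cluster(data.frame(seq = c(base, far),
                                   subpool_id = "P", count = c(5L, 4L)),
                        0.95)
  expect_equal(nrow(cl2$centroids), 2L)

  # all-identical input collapses with summed counts
  cl3 <- greedy_cluster(data.frame(seq = rep(base, 3),
                                   subpool_id = c("P", "Q", "R"),
                                   count = c(4L, 2L, 1L)), 0.95)
  expect_equal(nrow(cl3$centroids), 1L)
  expect_equal(sum(cl3$members$count), 7L)
})

test_that("clustering conserves reads and is idempotent on centroids", {
  set.seed(43)
  seeds <- rand_dna(6, 30)
  uniq <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    data.frame(seq = c(seeds[i], mutate_at(seeds[i], i %% 30 + 1L)),
               subpool_id = sprintf("P%d", 1:2),
               count = c(5L + i, 2L))
  }))
  cl <- greedy_cluster(uniq, 0.95)
  expect_equal(sum(cl$members$count), sum(uniq$count))
  # re-clustering the centroids returns them unchanged as singletons
  cl2 <- greedy_cluster(data.frame(seq = cl$centroids$centroid,
                                   subpool_id = "P", count = 1L), 0.95)
  expect_setequal(cl2$centroids$centroid, cl$centroids$centroid)
  expect_equal(nrow(cl2$centroids), nrow(cl$centroids))
})

test_that("border-zone DP still joins gapped near-identical sequences", {
  # a 1-nt deletion keeps DP identity above 0.95 while the Hamming
  # screen sees garbage; the unequal-length route must recover it
  set.seed(47)
  base <- rand_dna(1, 60)
  del <- paste0(substr(base, 1, 29), substr(base, 31, 60))
  expect_gte(pairwise_identity(base, del), 59 / 61)
  cl <- greedy_cluster(data.frame(seq = c(base, del), subpool_id = "P",
                                  count = c(9L, 1L)), 0.95)
  expect_equal(nrow(cl$centroids), 1L)
})

test_that("filter rules drop weak members and underpopulated clusters", {
  set.seed(51)
  cent <- rand_dna(1, 40)
  low <- mutate_at(cent, 5L)
  m <- data.frame(cluster = 1L,
                  seq = c(cent, cent, cent, low),
                  subpool_id = c("P1", "P2", "P3", "P4"),
                  count = c(50L, 30L, 20L, 4L))
  cl <- structure(list(
    centroids = data.frame(cluster = 1L, centroid = cent),
    members = m, domain_type = "AD", id_threshold = 0.95),
    class = "domain_clusters")

  # member with 4 reads < 5% of centroid total (100) is removed
  fl <- filter_clusters(cl, min_reads = 2, rel_frac = 0.05, min_wells = 3)
  expect_false(low %in% fl$members$seq)
  expect_equal(sort(unique(fl$members$subpool_id)), c("P1", "P2", "P3"))

  # cluster left in 2 wells after member filtering is dropped entirely
  # (centroid total 80, member total 3 < 5% of 80)
  m2 <- m[m$subpool_id %in% c("P1", "P2", "P4"), ]
  m2$count[m2$subpool_id == "P4"] <- 3L
  cl2 <- cl; cl2$members <- m2
  fl2 <- filter_clusters(cl2, min_reads = 2, rel_frac = 0.05,
                         min_wells = 3)
  expect_equal(nrow(fl2$members), 0L)
  expect_equal(nrow(fl2$centroids), 0L)

  # healthy cluster (members 100/50/10 in 3 wells) is retained intact
  m3 <- data.frame(cluster = 1L,
                   seq = c(cent, mutate_at(cent, 7L),
                           mutate_at(cent, 11L)),
                   subpool_id = c("P1", "P2", "P3"),
                   count = c(100L, 50L, 10L))
  cl3 <- cl; cl3$members <- m3
  fl3 <- filter_clusters(cl3, min_reads = 2, rel_frac = 0.05,
                         min_wells = 3)
  expect_equal(nrow(fl3$members), 3L)

  # the centroid itself is exempt from the relative-abundance rule
  m4 <- data.frame(cluster = 1L,
                   seq = c(cent, rep(mutate_at(cent, 9L), 3)),
                   subpool_id = c("P1", "P2", "P3", "P4"),
                   count = c(2L, 40L, 40L, 40L))
  cl4 <- cl; cl4$members <- m4
  fl4 <- filter_clusters(cl4, min_reads = 2, rel_frac = 0.05,
                         min_wells = 3)
  expect_true(cent %in% fl4$members$seq)
})

test_that("occurrence matrices enforce the minimum-well invariant", {
  counts <- rbind(a = c(1, 2, 3, 0), b = c(1, 0, 0, 0))
  colnames(counts) <- paste0("P", 1:4)
  v <- data.frame(variant_id = c("a", "b"), domain_type = "AD",
                  centroid = c("AAAA", "CCCC"))
  om <- occurrence_matrix(counts, v, min_wells = 3)
  expect_equal(nrow(om$counts), 1L)
  expect_equal(om$variants$variant_id, "a")
  expect_equal(om$n_subpools, 4L)
  expect_error(occurrence_matrix(counts, v[c(1, 1), ], min_wells = 0),
               "duplicate")
})

test_that("table merging unions variants over a shared subpool universe", {
  pools <- paste0("P", 1:6)
  mk <- function(ids, type) {
    counts <- matrix(rpois(length(ids) * 6, 2), nrow = length(ids),
                     dimnames = list(ids, pools))
    occurrence_matrix(counts,
                      data.frame(variant_id = ids, domain_type = type,
                                 centroid = rand_dna(length(ids), 10)),
                      min_wells = 0)
  }
  set.seed(61)
  ad <- mk(paste0("AD_", 1:5), "AD")
  ks <- mk(paste0("KS_", 1:3), "KS")
  merged <- merge_tables(list(ad, ks))
  expect_equal(nrow(merged$counts), 8L)
  expect_equal(Matrix::colSums(merged$counts),
               Matrix::colSums(ad$counts) + Matrix::colSums(ks$counts))
  # single table is the identity
  one <- merge_tables(list(ad))
  expect_equal(as.matrix(one$counts), as.matrix(ad$counts))
  # differing universes are a dimension error
  ks2 <- mk(paste0("KS_", 1:3), "KS")
  ks2$subpools <- paste0("Q", 1:6)
  colnames(ks2$counts) <- ks2$subpools
  expect_error(merge_tables(list(ad, ks2)), "dimension")
})

test_that("occurrence TSV round-trips", {
  set.seed(71)
  pools <- paste0("P", 1:5)
  counts <- matrix(rpois(15, 3), nrow = 3,
                   dimnames = list(paste0("v", 1:3), pools))
  om <- occurrence_matrix(counts,
                          data.frame(variant_id = paste0("v", 1:3),
                                     domain_type = "AD",
                                     centroid = rand_dna(3, 12)),
                          min_wells = 0)
  path <- tempfile(fileext = ".tsv")
  write_occurrence(om, path)
  back <- read_occurrence(path)
  expect_equal(as.matrix(back$counts), as.matrix(om$counts))
  expect_equal(back$variants, om$variants)
})
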