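#' Parameters for the partitioned-library simulator
#'
#' Describes a synthetic metagenomic clone library: a community of genomes
#' with log-normally skewed abundances, each carrying biosynthetic gene
#' clusters (BGCs) of several conserved domains, captured as ~38 kb inserts
#' that are arrayed into fixed-size subpools. Per-subpool amplification
#' dropout and per-base sequencing error reproduce the noise processes the
#' co-occurrence analysis must tolerate.
#'
#' Two presets mirror the library structures the method was designed for:
#' \code{"arizona"} (2304 subpools of ~5000 cosmids) and \code{"small"}
#' (384 subpools of 1000 clones, 20 single-BGC genomes), the latter sized
#' for desk-scale benchmarking.
#'
#' @param preset \code{NULL}, \code{"arizona"} or \code{"small"}.
#' @param n_genomes Number of source genomes.
#' @param abundance_sigma Log-normal sigma of genome abundances.
#' @param genome_length Genome size in bp (default 5 Mb, a mid-range soil
#'   bacterial genome; together with the default library size this keeps
#'   per-genome clone coverage in the regime where rare genomes sit near,
#'   but mostly above, the minimum-evidence threshold of the analysis).
#' @param n_bgcs_per_genome BGCs per genome.
#' @param domains_per_bgc Integer range \code{c(min, max)} of domains per
#'   BGC.
#' @param inter_domain_spacing Range (bp) of spacing between the starts of
#'   consecutive domains in a BGC.
#' @param domain_length Amplicon (trimmed-read) length in nt.
#' @param insert_mean,insert_sd Clone insert length distribution (bp),
#'   normal truncated to \code{[20000, 45000]}.
#' @param n_subpools Number of library subpools.
#' @param clones_per_subpool Clones dealt into each subpool.
#' @param dropout Probability that a present domain yields no amplicon in a
#'   subpool (i.i.d. per domain x subpool).
#' @param error_rate Per-base substitution probability in read mode.
#' @param reads_per_detection Integer range of reads emitted per detected
#'   (domain, subpool).
#' @param domain_type Domain label stamped on emitted variants.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class \code{"sim_params"}.
#' @export
sim_params <- function(preset = NULL, n_genomes = 20,
                       abundance_sigma = 1.5, genome_length = 5e6,
                       n_bgcs_per_genome = 1,
                       domains_per_bgc = c(4L, 4L),
                       inter_domain_spacing = c(2000L, 8000L),
                       domain_length = 230L,
                       insert_mean = 38000, insert_sd = 4000,
                       n_subpools = 2304L, clones_per_subpool = 5000L,
                       dropout = 0.1, error_rate = 0.005,
                       reads_per_detection = c(3L, 20L),
                       domain_type = "AD", seed = 1L) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("arizona", "small"))
    if (preset == "small") {
      n_subpools <- 384L
      clones_per_subpool <- 1000L
    }
    # "arizona" keeps the defaults: 2304 x 5000
  }
  p <- list(n_genomes = as.integer(n_genomes),
            abundance_sigma = abundance_sigma,
            genome_length = as.numeric(genome_length),
            n_bgcs_per_genome = as.integer(n_bgcs_per_genome),
            domains_per_bgc = as.integer(domains_per_bgc),
            inter_domain_spacing = as.integer(inter_domain_spacing),
            domain_length = as.integer(domain_length),
            insert_mean = insert_mean, insert_sd = insert_sd,
            n_subpools = as.integer(n_subpools),
            clones_per_subpool = as.integer(clones_per_subpool),
            dropout = dropout, error_rate = error_rate,
            reads_per_detection = as.integer(reads_per_detection),
            domain_type = domain_type, seed = as.integer(seed))
  stopifnot(p$n_genomes > 0, p$genome_length > 0,
            p$dropout >= 0, p$dropout < 1,
            p$error_rate >= 0, p$error_rate < 1,
            p$n_subpools > 0, p$clones_per_subpool > 0)
  class(p) <- "sim_params"
  p
}

## sample() treats a length-1 vector as 1:v; guard degenerate ranges
.sample_from <- function(v, n) {
  if (length(v) == 1L) rep(v, n) else sample(v, n, replace = TRUE)
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

## Deterministic subpool naming over 16x24 plates; index is 1-based,
## column-fastest, matching subpool_ids() ordering.
.sim_subpool_ids <- function(n_subpools) {
  k <- seq_len(n_subpools) - 1L
  plate <- sprintf("SIM%02d", k %/% 384L + 1L)
  within <- k %% 384L
  sprintf("%s_r%d_c%d", plate, within %/% 24L + 1L, within %% 24L + 1L)
}

#' Simulate a genome community with clustered biosynthetic domains
#'
#' Generates genomes as coordinate systems (sequence is materialised only
#' for the domain amplicons), places BGCs of several domains at the
#' configured spacings, and draws log-normal abundances normalised to sum
#' to 1. Domain sequences are independent random DNA, mutually far below
#' any clustering threshold by construction.
#'
#' @param params A \code{sim_params} object.
#' @return A list of class \code{"sim_community"} with \code{genomes}
#'   (data.frame \code{genome_id}, \code{abundance}, \code{length}),
#'   \code{domains} (data.frame \code{domain_id}, \code{genome_id},
#'   \code{bgc_id}, \code{start}, \code{end}, \code{seq}) and
#'   \code{params}.
#' @export
simulate_community <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  abund <- stats::rlnorm(params$n_genomes, 0, params$abundance_sigma)
  abund <- abund / sum(abund)
  genomes <- data.frame(genome_id = sprintf("g%03d",
                                            seq_len(params$n_genomes)),
                        abundance = abund,
                        length = params$genome_length)
  rows <- list()
  for (g in seq_len(params$n_genomes)) {
    for (b in seq_len(params$n_bgcs_per_genome)) {
      ndom <- .sample_from(params$domains_per_bgc[1L]:
                             params$domains_per_bgc[2L], 1L)
      spac <- .sample_from(params$inter_domain_spacing[1L]:
                             params$inter_domain_spacing[2L],
                           max(ndom - 1L, 0L))
      span <- sum(spac) + params$domain_length
      if (span > params$genome_length)
        stop("parameter error: BGC span exceeds genome length")
      start0 <- floor(stats::runif(1L, 0,
                                   params$genome_length - span + 1))
      starts <- start0 + cumsum(c(0L, spac))
      rows[[length(rows) + 1L]] <- data.frame(
        domain_id = sprintf("g%03d_b%d_d%d", g, b, seq_len(ndom)),
        genome_id = sprintf("g%03d", g),
        bgc_id = sprintf("g%03d_b%d", g, b),
        start = starts, end = starts + params$domain_length,
        seq = .random_dna(ndom, params$domain_length),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(genomes = genomes, domains = do.call(rbind, rows),
                 params = params),
            class = "sim_community")
}

#' Sample a partitioned clone library from a community
#'
#' Each clone draws its source genome proportionally to abundance, an
#' insert start uniform along the genome and an insert length from a
#' truncated normal; clones are dealt round-robin over a random permutation
#' into subpools, so subpool sizes differ by at most one.
#'
#' @param community A \code{sim_community}.
#' @return A data.frame clone table: \code{clone_id}, \code{genome_id},
#'   \code{start}, \code{end} (0-based half-open insert interval),
#'   \code{subpool_id}.
#' @export
simulate_library <- function(community) {
  stopifnot(inherits(community, "sim_community"))
  p <- community$params
  set.seed(p$seed + 1L)
  n_clones <- p$n_subpools * p$clones_per_subpool
  gidx <- sample.int(p$n_genomes, n_clones, replace = TRUE,
                     prob = community$genomes$abundance)
  len <- round(stats::rnorm(n_clones, p$insert_mean, p$insert_sd))
  len <- pmin(pmax(len, 20000), 45000)
  start <- floor(stats::runif(n_clones, 0, p$genome_length - len + 1))
  pool_of <- integer(n_clones)
  pool_of[sample.int(n_clones)] <- rep_len(seq_len(p$n_subpools), n_clones)
  data.frame(clone_id = seq_len(n_clones),
             genome_id = community$genomes$genome_id[gidx],
             start = start, end = start + len,
             subpool_id = .sim_subpool_ids(p$n_subpools)[pool_of],
             stringsAsFactors = FALSE)
}

## Clone indices fully containing each domain's amplicon interval.
.domain_clone_hits <- function(community, clone_table) {
  by_genome <- split(seq_len(nrow(clone_table)), clone_table$genome_id)
  d <- community$domains
  lapply(seq_len(nrow(d)), function(i) {
    idx <- by_genome[[d$genome_id[i]]]
    if (is.null(idx)) return(integer(0))
    idx[clone_table$start[idx] <= d$start[i] &
          clone_table$end[idx] >= d$end[i]]
  })
}

#' Ground truth of a simulated library
#'
#' Collects, for every unordered pair of domains on the same genome, the
#' number of clones and distinct subpools in which both are co-captured.
#' A pair is a true clustered pair when it is co-resident on at least one
#' clone.
#'
#' @param community A \code{sim_community}.
#' @param clone_table Output of [simulate_library()].
#' @return A list of class \code{"sim_truth"}: \code{domains},
#'   \code{clone_table}, \code{true_pairs} (data.frame \code{domain_a},
#'   \code{domain_b}, \code{bgc_a}, \code{bgc_b}, \code{n_clones_co},
#'   \code{n_subpools_co}) and \code{domain_hits} (clone indices per
#'   domain).
#' @export
simulated_truth <- function(community, clone_table) {
  hits <- .domain_clone_hits(community, clone_table)
  d <- community$domains
  pairs <- list()
  for (g in unique(d$genome_id)) {
    idx <- which(d$genome_id == g)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        ia <- idx[a]; ib <- idx[b]
        co <- intersect(hits[[ia]], hits[[ib]])
        if (length(co) == 0L) next
        pairs[[length(pairs) + 1L]] <- data.frame(
          domain_a = min(d$domain_id[ia], d$domain_id[ib]),
          domain_b = max(d$domain_id[ia], d$domain_id[ib]),
          bgc_a = d$bgc_id[ia], bgc_b = d$bgc_id[ib],
          n_clones_co = length(co),
          n_subpools_co = length(unique(clone_table$subpool_id[co])),
          stringsAsFactors = FALSE)
      }
    }
  }
  true_pairs <- if (length(pairs) > 0L) do.call(rbind, pairs) else
    data.frame(domain_a = character(), domain_b = character(),
               bgc_a = character(), bgc_b = character(),
               n_clones_co = integer(), n_subpools_co = integer())
  structure(list(domains = d, clone_table = clone_table,
                 true_pairs = true_pairs, domain_hits = hits),
            class = "sim_truth")
}

#' Probability that one insert co-captures two loci d bp apart
#'
#' For an insert of length L whose position is uniform conditional on
#' covering the first locus, the chance it also covers a second locus d bp
#' away is \code{max(0, (L - d) / L)} — the geometric origin of the
#' co-occurrence signal.
#'
#' @param d Distance between loci in bp (\code{>= 0}); vectorised.
#' @param L Insert length in bp (\code{> 0}).
#' @return Co-capture probability in \code{[0, 1]}.
#' @export
cocapture_probability <- function(d, L) {
  stopifnot(all(d >= 0), L > 0)
  pmax(0, (L - d) / L)
}

## Detection table: for each domain, the subpools where at least one clone
## carries it and a Bernoulli(1 - dropout) amplification succeeded.
## Drawn in a fixed order so direct and read modes see identical truth.
.sim_detections <- function(community, clone_table, truth) {
  p <- community$params
  d <- community$domains
  lapply(seq_len(nrow(d)), function(i) {
    pools <- sort(unique(clone_table$subpool_id[truth$domain_hits[[i]]]))
    if (length(pools) == 0L) return(character(0))
    pools[stats::runif(length(pools)) >= p$dropout]
  })
}

.mutate_reads <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  L <- nchar(seqs[1L])
  nerr <- stats::rbinom(length(seqs), L, error_rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(L, nerr[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (pp in pos) {
      ch[pp] <- sample(setdiff(c("A", "C", "G", "T"), ch[pp]), 1L)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Emit simulated observations: occurrence matrix or barcoded reads
#'
#' In \code{"direct"} mode the detection table (clone content minus
#' amplification dropout) is returned as an \code{occurrence_matrix}. In
#' \code{"reads"} mode each detection is expanded into barcoded paired-end
#' reads (forward read: column barcode + primer pad + domain sequence with
#' per-base substitution errors; reverse read: row barcode + reverse
#' complement) under a generated [subpool_scheme()], so the demultiplexing
#' and clustering stages can be exercised end to end. Both modes draw the
#' detection table identically for a given seed.
#'
#' @param community A \code{sim_community}.
#' @param clone_table Output of [simulate_library()].
#' @param truth Output of [simulated_truth()].
#' @param mode \code{"direct"} or \code{"reads"}.
#' @param min_wells Minimum occupied subpools per variant retained in the
#'   direct-mode matrix (default 3, mirroring the variant-table filter).
#' @param out_dir In read mode, directory to write \code{R1.fastq},
#'   \code{R2.fastq} and \code{scheme.tsv} (\code{NULL}: in-memory only).
#' @return Direct mode: an \code{occurrence_matrix} whose variant ids are
#'   the true domain ids. Read mode: a list \code{fwd}, \code{rev}
#'   (character vectors), \code{scheme}, \code{detections}.
#' @export
emit_observations <- function(community, clone_table, truth,
                              mode = c("direct", "reads"),
                              min_wells = 3L, out_dir = NULL) {
  mode <- match.arg(mode)
  p <- community$params
  set.seed(p$seed + 2L)
  det <- .sim_detections(community, clone_table, truth)
  d <- community$domains
  pools <- .sim_subpool_ids(p$n_subpools)
  if (mode == "direct") {
    i <- rep(seq_len(nrow(d)), lengths(det))
    j <- match(unlist(det), pools)
    counts <- Matrix::sparseMatrix(
      i = i, j = j, x = 1L,
      dims = c(nrow(d), length(pools)),
      dimnames = list(d$domain_id, pools))
    variants <- data.frame(variant_id = d$domain_id,
                           domain_type = p$domain_type,
                           centroid = d$seq, stringsAsFactors = FALSE)
    return(occurrence_matrix(counts, variants, min_wells = min_wells))
  }
  if (p$n_subpools > 384L)
    stop("read mode supports at most one 384-subpool plate")
  bcs <- unique(.random_dna(200L, 8L))[1:40]
  scheme <- subpool_scheme(plate_id = "SIM01",
                           column_barcodes = bcs[1:24],
                           row_barcodes = bcs[25:40],
                           primer_len = 20L,
                           total_len = 20L + p$domain_length,
                           domain_type = p$domain_type)
  primer_pad <- .random_dna(1L, scheme$primer_len)
  k <- seq_len(p$n_subpools) - 1L
  row_of <- k %/% 24L + 1L; col_of <- k %% 24L + 1L
  names(row_of) <- names(col_of) <- pools
  det_dom <- rep(seq_len(nrow(d)), lengths(det))
  det_sp <- unlist(det, use.names = FALSE)
  nr <- .sample_from(p$reads_per_detection[1L]:p$reads_per_detection[2L],
                     length(det_dom))
  read_dom <- rep(det_dom, nr)
  read_sp <- rep(det_sp, nr)
  dom_reads <- .mutate_reads(d$seq[read_dom], p$error_rate)
  fwd <- paste0(scheme$column_barcodes[col_of[read_sp]], primer_pad,
                dom_reads)
  rev <- paste0(scheme$row_barcodes[row_of[read_sp]],
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAStringSet(dom_reads))))
  out <- list(fwd = fwd, rev = rev, scheme = scheme, detections = det)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_fastq(fwd, file.path(out_dir, "R1.fastq"), "sim")
    .write_fastq(rev, file.path(out_dir, "R2.fastq"), "sim")
    write_scheme(scheme, file.path(out_dir, "scheme.tsv"))
  }
  out
}

.write_fastq <- function(seqs, path, prefix) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- sprintf("%s_%06d", prefix, seq_along(ss))
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Score linkage predictions against simulated ground truth
#'
#' Maps predicted variant pairs back to true domains (exact sequence match,
#' falling back to >= 0.95 global identity), then computes precision
#' against all true clustered pairs and recall against the detectable ones
#' (true pairs co-captured in at least \code{min_shared} distinct
#' subpools). Pairs whose two variants map to the same domain are split
#' artifacts of one locus, not clustering claims, and are excluded; pairs
#' with an unmappable variant are excluded and counted.
#'
#' @param links A \code{link_set} (significant rows are scored) or a
#'   data.frame with columns \code{variant_a}, \code{variant_b}.
#' @param truth A \code{sim_truth}.
#' @param variants The \code{variants} data.frame of the occurrence matrix
#'   the links came from (provides centroids for the mapping).
#' @param min_shared Detectability cutoff for the recall denominator
#'   (default 3).
#' @return A list \code{precision}, \code{recall}, \code{n_predicted},
#'   \code{n_true_detectable}, \code{n_unmapped}, \code{zero_support}
#'   (\code{TRUE} when nothing was predicted, in which case precision is
#'   reported as 1).
#' @export
score_recovery <- function(links, truth, variants, min_shared = 3L) {
  stopifnot(inherits(truth, "sim_truth"))
  df <- as.data.frame(links)
  if ("significant" %in% names(df)) df <- df[df$significant, , drop = FALSE]
  map <- .map_variants_to_domains(variants, truth$domains)
  da <- map[df$variant_a]; db <- map[df$variant_b]
  unmapped <- is.na(da) | is.na(db)
  selfpair <- !unmapped & da == db
  da <- da[!unmapped & !selfpair]; db <- db[!unmapped & !selfpair]
  pred <- unique(paste(pmin(da, db), pmax(da, db), sep = "\r"))
  truth_all <- paste(truth$true_pairs$domain_a, truth$true_pairs$domain_b,
                     sep = "\r")
  detectable <- truth_all[truth$true_pairs$n_subpools_co >= min_shared]
  zero <- length(pred) == 0L
  precision <- if (zero) 1 else mean(pred %in% truth_all)
  recall <- if (length(detectable) == 0L) NA_real_ else
    mean(detectable %in% pred)
  list(precision = precision, recall = recall,
       n_predicted = length(pred),
       n_true_detectable = length(detectable),
       n_unmapped = sum(unmapped), zero_support = zero)
}

.map_variants_to_domains <- function(variants, domains) {
  map <- domains$domain_id[match(variants$centroid, domains$seq)]
  todo <- which(is.na(map))
  for (i in todo) {
    ids <- .identities_to(variants$centroid[i], domains$seq)
    j <- which.max(ids)
    if (ids[j] >= 0.95) map[i] <- domains$domain_id[j]
  }
  names(map) <- variants$variant_id
  map
}

#' Run a full simulation and write its artifacts
#'
#' Orchestrates community, library, truth and observation generation and,
#' when \code{out_dir} is given, writes the truth tables, the occurrence
#' matrix (direct mode) or FASTQ + scheme (read mode), and a JSON manifest
#' recording parameters and seed.
#'
#' @param params A \code{sim_params}.
#' @param mode \code{"direct"} or \code{"reads"}.
#' @param out_dir Output directory, or \code{NULL} for in-memory results.
#' @return A list \code{community}, \code{clone_table}, \code{truth},
#'   \code{observations}.
#' @export
simulate_run <- function(params, mode = c("direct", "reads"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  community <- simulate_community(params)
  clone_table <- simulate_library(community)
  truth <- simulated_truth(community, clone_table)
  obs <- emit_observations(community, clone_table, truth, mode = mode,
                           out_dir = if (mode == "reads") out_dir else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(community$domains,
                       file.path(out_dir, "truth_domains.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$true_pairs,
                       file.path(out_dir, "truth_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clone_table,
                       file.path(out_dir, "truth_clones.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (mode == "direct")
      write_occurrence(obs, file.path(out_dir, "occurrence.tsv"))
    jsonlite::write_json(unclass(params),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(community = community, clone_table = clone_table, truth = truth,
       observations = obs)
}
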