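#' Coverage-based sequencing-output and genome-frequency extrapolation
#'
#' From the mean depth of coverage a contig attained in a shallow
#' untargeted sequencing run, extrapolate (a) the sequencing output needed
#' to bring that contig to a target depth and (b) the frequency of its
#' source genome in the library, assuming a fixed genome size. Depth is the
#' mean per-base coverage of the contig; the read mapping that produces it
#' is upstream of this module.
#'
#' @param mean_depth Observed mean fold-coverage (> 0); vectorised.
#' @param sequenced_output Total sequencing output that produced the
#'   observed depth, in Gbp (default 15.5).
#' @param target_depth Desired fold-coverage (default 20).
#' @param genome_size Assumed source-genome size in Gbp (default 0.01,
#'   i.e. 10 Mbp).
#' @return \code{required_output}: Gbp needed to reach
#'   \code{target_depth}; \code{genome_frequency}: fraction of the library
#'   attributable to the source genome.
#' @examples
#' required_output(20)            # already at target: 15.5
#' required_output(0.31)          # 1000 Gbp = 1 Tbp
#' genome_frequency(15.5)         # 0.01 = 1%
#' @name abundance
NULL

#' @rdname abundance
#' @export
required_output <- function(mean_depth, sequenced_output = 15.5,
                            target_depth = 20) {
  if (any(mean_depth <= 0)) stop("mean_depth must be positive")
  sequenced_output / mean_depth * target_depth
}

#' @rdname abundance
#' @export
genome_frequency <- function(mean_depth, sequenced_output = 15.5,
                             genome_size = 0.01) {
  if (any(mean_depth <= 0)) stop("mean_depth must be positive")
  mean_depth * genome_size / sequenced_output
}

#' Annotate a depth table with extrapolated output and frequency
#'
#' @param depth A data.frame with columns \code{contig_id},
#'   \code{mean_depth}.
#' @inheritParams abundance
#' @return The input with added columns \code{required_output_gbp} and
#'   \code{est_frequency}.
#' @export
abundance_table <- function(depth, sequenced_output = 15.5,
                            target_depth = 20, genome_size = 0.01) {
  stopifnot(all(c("contig_id", "mean_depth") %in% names(depth)))
  depth$required_output_gbp <- required_output(depth$mean_depth,
                                               sequenced_output,
                                               target_depth)
  depth$est_frequency <- genome_frequency(depth$mean_depth,
                                          sequenced_output, genome_size)
  depth
}
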