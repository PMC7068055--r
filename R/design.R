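#' Oddball design parameters
#'
#' Defaults reproduce the study session: four blocks of 280 trials, 80%
#' standards and 20% novels (half emotionally negative, half neutral), each
#' of the 56 novel identities presented exactly once per block, every novel
#' followed by at least two standards, and a stimulus onset asynchrony drawn
#' from 1800 to 2080 ms in 40-ms steps.
#'
#' @param blocks number of blocks.
#' @param trials_per_block trials per block.
#' @param novels_emotional,novels_neutral novel trials per block by category.
#' @param soa_ms permitted stimulus onset asynchronies (ms).
#' @param lead_in_standards minimum number of standards opening each block.
#' @param min_standards_after_novel minimum standards following each novel.
#' @return A list of design parameters.
#' @export
design_config <- function(blocks = 4L,
                          trials_per_block = 280L,
                          novels_emotional = 28L,
                          novels_neutral = 28L,
                          soa_ms = seq(1800L, 2080L, by = 40L),
                          lead_in_standards = 2L,
                          min_standards_after_novel = 2L) {
  list(blocks = as.integer(blocks),
       trials_per_block = as.integer(trials_per_block),
       novels_emotional = as.integer(novels_emotional),
       novels_neutral = as.integer(novels_neutral),
       soa_ms = as.integer(soa_ms),
       lead_in_standards = as.integer(lead_in_standards),
       min_standards_after_novel = as.integer(min_standards_after_novel))
}

#' Generate a pseudo-randomized oddball sound sequence
#'
#' Constructive, rejection-free placement: novel slots are drawn so that each
#' block opens with the required standards and every novel is followed by the
#' required number of standards; novel identities (fixed emotion category per
#' identity) are then shuffled into the slots, once per identity per block.
#' Identical seeds give identical sequences.
#'
#' @param config design parameters, see [design_config()].
#' @param seed integer seed; the sequence is a deterministic function of it.
#' @return A `trial_sequence` data frame with columns `block_index`,
#'   `trial_index`, `trial_type`, `novel_id`, `soa_ms`, `onset_ms`
#'   (onset cumulative within block, first trial at 0).
#' @export
generate_sound_sequence <- function(config = design_config(), seed = 1L) {
  n <- config$trials_per_block
  m <- config$novels_emotional + config$novels_neutral
  gap <- config$min_standards_after_novel
  lead <- config$lead_in_standards
  if (m > 0 && n < lead + m * (1L + gap)) {
    stopf(paste0("infeasible design: %d trials/block cannot hold %d novels ",
                 "with %d lead-in standards and %d standards after each ",
                 "novel (need >= %d trials)"),
          n, m, lead, gap, lead + m * (1L + gap))
  }
  if (length(config$soa_ms) < 1) stopf("soa_ms must be non-empty")

  with_seed(seed, {
    blocks <- lapply(seq_len(config$blocks), function(b) {
      type <- rep("standard", n)
      novel_id <- rep(NA_integer_, n)
      if (m > 0) {
        # positions q_i >= lead+1 with q_{i+1} - q_i >= gap+1 and
        # q_m <= n - gap; sample the gap-removed coordinates with
        # replacement and sort (rejection-free, feasible at any seed)
        lo <- lead + 1L
        hi <- n - gap - (gap + 1L) * (m - 1L)
        r <- sort(sample.int(hi - lo + 1L, m, replace = TRUE) + lo - 1L)
        q <- r + (gap + 1L) * (seq_len(m) - 1L)
        emo_slots <- sort(sample(q, config$novels_emotional))
        neu_slots <- setdiff(q, emo_slots)
        type[emo_slots] <- "novel_emotional"
        type[neu_slots] <- "novel_neutral"
        novel_id[emo_slots] <- sample(seq_len(config$novels_emotional))
        novel_id[neu_slots] <- config$novels_emotional +
          sample(seq_len(config$novels_neutral))
      }
      soa <- sample(config$soa_ms, n, replace = TRUE)
      data.frame(block_index = b,
                 trial_index = seq_len(n),
                 trial_type = type,
                 novel_id = novel_id,
                 soa_ms = soa,
                 onset_ms = cumsum(c(0L, soa[-n])),
                 stringsAsFactors = FALSE)
    })
    seq_df <- do.call(rbind, blocks)
    class(seq_df) <- c("trial_sequence", "data.frame")
    attr(seq_df, "config") <- config
    validate_trial_sequence(seq_df, config)
    seq_df
  })
}

#' Check the invariants of an oddball trial sequence
#'
#' Verifies per-block trial counts, the once-per-block presentation of every
#' novel identity, the post-novel standard spacing, and SOA membership.
#'
#' @param sequence a `trial_sequence`.
#' @param config the design parameters the sequence must satisfy.
#' @return Invisibly `TRUE`; otherwise an error describing the violation.
#' @export
validate_trial_sequence <- function(sequence,
                                    config = attr(sequence, "config")) {
  stopifnot(is.data.frame(sequence))
  m <- config$novels_emotional + config$novels_neutral
  for (b in unique(sequence$block_index)) {
    blk <- sequence[sequence$block_index == b, ]
    if (nrow(blk) != config$trials_per_block)
      stopf("block %d has %d trials, expected %d", b, nrow(blk),
            config$trials_per_block)
    if (sum(blk$trial_type == "novel_emotional") != config$novels_emotional ||
        sum(blk$trial_type == "novel_neutral") != config$novels_neutral)
      stopf("block %d novel counts do not match the design", b)
    ids <- blk$novel_id[!is.na(blk$novel_id)]
    if (m > 0 && !setequal(ids, seq_len(m)))
      stopf("block %d does not present each novel identity exactly once", b)
    nov <- which(blk$trial_type != "standard")
    for (q in nov) {
      after <- seq(q + 1L, length.out = config$min_standards_after_novel)
      if (max(after) > nrow(blk) ||
          any(blk$trial_type[after] != "standard"))
        stopf("novel at block %d trial %d lacks %d following standards",
              b, q, config$min_standards_after_novel)
    }
    if (m > 0 && config$lead_in_standards > 0 &&
        any(blk$trial_type[seq_len(config$lead_in_standards)] != "standard"))
      stopf("block %d does not open with %d standards", b,
            config$lead_in_standards)
  }
  if (!all(sequence$soa_ms %in% config$soa_ms))
    stopf("SOA values outside the permitted set")
  invisible(TRUE)
}

#' Summarize a session's trial accounting
#'
#' @param sequence a `trial_sequence`.
#' @return List with session totals (`standards`, `novels`,
#'   `novels_emotional`, `novels_neutral`, `novels_per_block`,
#'   `repetitions_per_novel`) and `expected_block_duration_min`, the design's
#'   expected block length in minutes (mean SOA times trials per block).
#' @export
session_summary <- function(sequence) {
  config <- attr(sequence, "config")
  tab <- table(sequence$trial_type)
  reps <- if (any(!is.na(sequence$novel_id))) {
    as.integer(unique(table(sequence$novel_id)))
  } else integer(0)
  list(
    standards = as.integer(tab["standard"] %||% 0L),
    novels = sum(sequence$trial_type != "standard"),
    novels_emotional = as.integer(tab["novel_emotional"] %||% 0L),
    novels_neutral = as.integer(tab["novel_neutral"] %||% 0L),
    novels_per_block = sum(sequence$trial_type != "standard") /
      length(unique(sequence$block_index)),
    repetitions_per_novel = reps,
    expected_block_duration_min =
      mean(config$soa_ms) * config$trials_per_block / 60000
  )
}
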