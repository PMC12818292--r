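#' Count whitespace-delimited words
#'
#' Tokenizes an utterance by runs of whitespace and counts the non-empty
#' tokens. Punctuation is not stripped, matching the plain whitespace
#' tokenization used on checked transcripts.
#'
#' @param utterance character vector (possibly empty strings).
#' @return integer vector of word counts.
#' @export
#' @examples
#' count_words("the odd one is two") # 5
#' count_words("  I'm   sure ")      # 2
count_words <- function(utterance) {
  if (!is.character(utterance)) utterance <- as.character(utterance)
  vapply(strsplit(trimws(utterance), "\\s+"),
         function(tok) sum(nzchar(tok)), integer(1))
}

#' Default confidence/certainty lexicon
#'
#' A small editable list of common confidence, certainty, and uncertainty
#' expressions used for transcript counting. It is a configuration
#' artifact, seeded with typical phrases; studies should adapt it to their
#' corpus.
#'
#' @return character vector of lowercase phrases.
#' @export
default_confidence_lexicon <- function() {
  c("i'm sure", "i am sure", "i'm not sure", "i am not sure",
    "i'm confident", "i am confident", "i'm certain", "i am certain",
    "not sure", "pretty sure", "quite sure", "really sure",
    "maybe", "definitely", "probably", "certainly",
    "i think", "i guess", "i believe", "no idea", "i don't know",
    "could be", "must be")
}

#' Count confidence-lexicon matches in an utterance
#'
#' Case-insensitive phrase counting with leftmost-longest, non-overlapping
#' matching: at each position the longest matching phrase wins and the text
#' it covers cannot contribute to another match, so "i'm not sure" counts
#' once even when "not sure" is also in the lexicon. Matches must fall on
#' word boundaries.
#'
#' @param utterance character vector.
#' @param lexicon non-empty character vector of lowercase phrases (default
#'   [default_confidence_lexicon()]).
#' @return integer vector of phrase counts.
#' @export
#' @examples
#' count_lexicon_matches("I'm sure it's lemon, maybe peach") # 2
count_lexicon_matches <- function(utterance, lexicon = default_confidence_lexicon()) {
  if (length(lexicon) == 0 || all(!nzchar(lexicon))) {
    stop_olf("lexicon must be a non-empty phrase list",
             class = "olfdyad_config_error")
  }
  lexicon <- tolower(lexicon)
  word_chars <- "[a-z0-9']"
  patterns <- vapply(lexicon, function(ph) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", ph)
    paste0("(?<!", word_chars, ")", esc, "(?!", word_chars, ")")
  }, character(1))
  vapply(tolower(as.character(utterance)), function(txt) {
    if (!nzchar(trimws(txt))) return(0L)
    hits <- do.call(rbind, lapply(seq_along(patterns), function(i) {
      mm <- gregexpr(patterns[i], txt, perl = TRUE)[[1]]
      if (mm[1] == -1) return(NULL)
      data.frame(start = as.integer(mm),
                 len = attr(mm, "match.length"))
    }))
    if (is.null(hits)) return(0L)
    hits <- hits[order(hits$start, -hits$len), , drop = FALSE]
    count <- 0L
    last_end <- 0L
    for (j in seq_len(nrow(hits))) {
      if (hits$start[j] > last_end) {
        count <- count + 1L
        last_end <- hits$start[j] + hits$len[j] - 1L
      }
    }
    count
  }, integer(1), USE.NAMES = FALSE)
}

#' Decompose per-trial word use into within/between/imbalance components
#'
#' For conflict trials, splits each trial's total word count into a
#' within-dyad deviation (the trial's words minus that dyad's mean over its
#' conflict trials), a between-dyad component (the dyad mean centered on
#' the grand mean of dyad means) and a per-dyad talkativeness-imbalance
#' index |mean_1 - mean_2| / (mean_1 + mean_2) computed from the members'
#' mean word counts. The identity
#' `words = grand_mean + between + within_dev` holds exactly per trial.
#'
#' @param conflict_trials data.frame with columns `dyad_id`, `trial_index`,
#'   `words_a`, `words_b` (per-member words in the trial); total words are
#'   `words_a + words_b`.
#' @param grand_mean optional grand mean to center on; default is the mean
#'   of the dyad means.
#' @return data.frame with `dyad_id`, `trial_index`, `words_total`,
#'   `within_dev`, `between`, `imbalance`, plus the `grand_mean` used as an
#'   attribute.
#' @export
word_use_components <- function(conflict_trials, grand_mean = NULL) {
  req <- c("dyad_id", "trial_index", "words_a", "words_b")
  miss <- setdiff(req, names(conflict_trials))
  if (length(miss)) {
    stop_olf("missing columns: ", paste(miss, collapse = ", "),
             class = "olfdyad_schema_error")
  }
  if (nrow(conflict_trials) == 0) {
    stop_olf("no conflict trials", class = "olfdyad_empty_input")
  }
  x <- conflict_trials
  x$words_total <- x$words_a + x$words_b
  dyad_mean <- tapply(x$words_total, x$dyad_id, mean)
  gm <- grand_mean %||% mean(dyad_mean)
  mean_a <- tapply(x$words_a, x$dyad_id, mean)
  mean_b <- tapply(x$words_b, x$dyad_id, mean)
  if (any(mean_a + mean_b == 0)) {
    stop_olf("imbalance undefined: a dyad uttered no words at all",
             class = "olfdyad_undefined_ratio")
  }
  id <- as.character(x$dyad_id)
  out <- data.frame(
    dyad_id = x$dyad_id,
    trial_index = x$trial_index,
    words_total = x$words_total,
    within_dev = x$words_total - dyad_mean[id],
    between = dyad_mean[id] - gm,
    imbalance = abs(mean_a[id] - mean_b[id]) / (mean_a[id] + mean_b[id])
  )
  rownames(out) <- NULL
  attr(out, "grand_mean") <- gm
  out
}

#' Classify conflict outcomes by relative talkativeness
#'
#' For each conflict trial, labels whether the member whose private answer
#' became the joint answer was the more or the less talkative member of the
#' dyad on that trial (by word count). Trials with equal word counts, and
#' trials whose joint answer matches neither private answer (possible when
#' the pair settles on a third alternative), are labelled
#' `tie_or_excluded`.
#'
#' @param words_a,words_b per-trial word counts of the two members.
#' @param answer_a,answer_b the two private answers (must differ:
#'   conflict trials only).
#' @param joint_answer the dyad's joint answer.
#' @return character vector with values `more_talkative_won`,
#'   `less_talkative_won`, `tie_or_excluded`.
#' @export
talkative_outcome <- function(words_a, words_b, answer_a, answer_b, joint_answer) {
  n <- length(words_a)
  if (any(lengths(list(words_b, answer_a, answer_b, joint_answer)) != n)) {
    stop_olf("inputs must be aligned", class = "olfdyad_alignment_error")
  }
  if (any(as.character(answer_a) == as.character(answer_b))) {
    stop_olf("talkative_outcome is defined for conflict trials only")
  }
  winner_a <- as.character(joint_answer) == as.character(answer_a)
  winner_b <- as.character(joint_answer) == as.character(answer_b)
  out <- rep("tie_or_excluded", n)
  no_winner <- !winner_a & !winner_b
  if (any(no_winner)) {
    warning(sum(no_winner), " trial(s) where the joint answer matches neither member; excluded",
            call. = FALSE)
  }
  decided <- (winner_a | winner_b) & words_a != words_b
  more_is_a <- words_a > words_b
  won_more <- (winner_a & more_is_a) | (winner_b & !more_is_a)
  out[decided & won_more] <- "more_talkative_won"
  out[decided & !won_more] <- "less_talkative_won"
  out
}
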