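#' Pause/phone profile for synthetic alignments
#'
#' Describes the inter-word gap distribution and the phoneme-class mix used
#' when generating forced-alignment-style word and phone tiers.
#'
#' @param gap_mean_s,gap_sd_s Log-normal-ish inter-word gap location/spread
#'   (gaps are drawn log-normal with this mean/sd on the natural scale).
#' @param p_gap Probability that a word boundary carries a non-negligible gap
#'   (otherwise the gap is a short articulatory break < 50 ms).
#' @param gaps Optional explicit numeric vector of gaps (seconds), recycled
#'   across word boundaries; overrides the stochastic gap model (useful for
#'   deterministic fixtures).
#' @param class_mix Named probability vector over the six phoneme classes.
#' @param phones_per_word Integer range (min, max) of phones per word.
#' @param phone_dur_s Range (min, max) of individual phone durations.
#' @return Object of class `pause_profile`.
#' @export
pause_profile <- function(gap_mean_s = 0.35, gap_sd_s = 0.25, p_gap = 0.5,
                          gaps = NULL,
                          class_mix = c(occlusive = 0.20, fricative = 0.18,
                                        nasal = 0.10, liquid = 0.12,
                                        semivowel = 0.05, oral_vowel = 0.35),
                          phones_per_word = c(2L, 6L),
                          phone_dur_s = c(0.04, 0.20)) {
  stopifnot(setequal(names(class_mix), PHONE_CLASSES))
  if (!is.null(gaps) && any(gaps < 0)) stopf("gaps must be non-negative")
  if (any(phone_dur_s <= 0)) stopf("phone durations must be positive")
  structure(list(gap_mean_s = gap_mean_s, gap_sd_s = gap_sd_s, p_gap = p_gap,
                 gaps = gaps, class_mix = class_mix / sum(class_mix),
                 phones_per_word = phones_per_word, phone_dur_s = phone_dur_s),
            class = "pause_profile")
}

#' Generate a synthetic word/phone alignment
#'
#' Emulates forced-aligner output: time-ordered, non-overlapping word
#' intervals separated by gaps drawn from the pause profile, each word tiled
#' exactly by its phone intervals. Phone labels are sampled from the French
#' phone inventory according to the class mix.
#'
#' @param word_count Number of words (>= 1).
#' @param profile A [pause_profile()].
#' @param seed Integer seed.
#' @param lead_s Leading silence before the first word.
#' @return List with `words` (tmin, tmax, label), `phones` (tmin, tmax,
#'   label, class, word) and `duration` (seconds, covering all intervals).
#' @export
generate_alignment <- function(word_count, profile = pause_profile(), seed = 1L,
                               lead_s = 0.15) {
  if (word_count < 1) stopf("word_count must be >= 1")
  stopifnot(inherits(profile, "pause_profile"))
  set.seed(seed)
  map <- phone_class_map()
  phones_by_class <- split(names(map), map)
  n_gaps <- word_count - 1L
  gaps <- if (!is.null(profile$gaps)) {
    rep_len(profile$gaps, max(n_gaps, 0L))
  } else if (n_gaps > 0) {
    has_gap <- runif(n_gaps) < profile$p_gap
    g <- runif(n_gaps, 0.005, 0.05)
    if (any(has_gap)) {
      mu <- log(profile$gap_mean_s^2 /
                  sqrt(profile$gap_mean_s^2 + profile$gap_sd_s^2))
      s2 <- sqrt(log(1 + profile$gap_sd_s^2 / profile$gap_mean_s^2))
      g[has_gap] <- rlnorm(sum(has_gap), mu, s2)
    }
    g
  } else numeric(0)
  words <- list(); phones <- list()
  cursor <- lead_s
  for (w in seq_len(word_count)) {
    n_ph <- sample(profile$phones_per_word[1]:profile$phones_per_word[2], 1)
    cls <- sample(PHONE_CLASSES, n_ph, replace = TRUE, prob = profile$class_mix)
    labs <- vapply(cls, function(cl) sample(phones_by_class[[cl]], 1), "")
    durs <- runif(n_ph, profile$phone_dur_s[1], profile$phone_dur_s[2])
    ends <- cursor + cumsum(durs)
    starts <- c(cursor, head(ends, -1))
    word_label <- paste0("w", w)
    phones[[w]] <- data.frame(tmin = starts, tmax = ends, label = unname(labs),
                              class = cls, word = word_label,
                              stringsAsFactors = FALSE)
    words[[w]] <- data.frame(tmin = cursor, tmax = ends[n_ph],
                             label = word_label, stringsAsFactors = FALSE)
    cursor <- ends[n_ph] + if (w <= n_gaps) gaps[w] else 0
  }
  words <- do.call(rbind, words); rownames(words) <- NULL
  phones <- do.call(rbind, phones); rownames(phones) <- NULL
  if (any(words$tmax < words$tmin) || any(phones$tmax < phones$tmin)) {
    stopf("negative interval durations generated")
  }
  list(words = words, phones = phones, duration = max(words$tmax) + lead_s)
}

#' Write an alignment's tiers to a TextGrid file
#'
#' @param alignment Result of [generate_alignment()] (or any list with
#'   `words`/`phones` interval data frames and a `duration`).
#' @param path Output TextGrid path (long format).
#' @return `path`, invisibly.
#' @export
write_alignment_textgrid <- function(alignment, path) {
  write_textgrid(list(words = alignment$words,
                      phones = alignment$phones[, c("tmin", "tmax", "label")]),
                 path, duration = alignment$duration)
}

#' Read an alignment back from a TextGrid file
#'
#' Reconstructs the `words`/`phones` structure (phone classes re-derived from
#' the phone label resource; phones assigned to the word interval containing
#' their midpoint).
#'
#' @param path TextGrid path.
#' @param class_map Phone-to-class map, default [phone_class_map()].
#' @return List with `words`, `phones`, `duration`.
#' @export
read_alignment_textgrid <- function(path, class_map = phone_class_map()) {
  tiers <- read_textgrid(path)
  if (!all(c("words", "phones") %in% names(tiers))) {
    stopf("TextGrid must contain 'words' and 'phones' tiers")
  }
  words <- tiers$words
  phones <- tiers$phones
  phones$class <- unname(class_map[phones$label])
  mid <- (phones$tmin + phones$tmax) / 2
  idx <- vapply(mid, function(m) {
    w <- which(words$tmin <= m + 1e-9 & words$tmax >= m - 1e-9)
    if (length(w)) w[1] else NA_integer_
  }, 1L)
  phones$word <- words$label[idx]
  list(words = words, phones = phones, duration = attr(tiers, "duration"))
}
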