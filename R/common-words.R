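# Fixed list of 100 common English monosyllables. Doubles as the default
# common-word list of the complexity scorer and as the filler vocabulary of
# the synthetic corpus generator, so the boundary between "simple" and
# "complex" tokens is crisp in tests. Every entry counts as exactly one
# syllable under count_syllables(); a unit test enforces this.
.common_words <- c(
  "the", "of", "and", "a", "to", "in", "is", "was", "for", "on",
  "as", "with", "at", "by", "an", "be", "this", "from", "or", "one",
  "had", "not", "but", "what", "all", "were", "we", "when", "your", "can",
  "said", "there", "use", "each", "which", "she", "do", "how", "their", "if",
  "will", "up", "out", "then", "them", "these", "so", "some", "her", "would",
  "make", "like", "him", "time", "has", "look", "two", "more", "go", "see",
  "no", "way", "could", "my", "than", "first", "been", "call", "who", "its",
  "now", "find", "long", "down", "day", "did", "get", "come", "made", "may",
  "part", "new", "sound", "take", "place", "live", "me", "back", "give", "most",
  "name", "good", "man", "think", "say", "great", "where", "through", "much", "right"
)

#' Default common-word list
#'
#' One hundred frequent English monosyllables. Words on this list always score
#' zero under [score_complexity()]; the synthetic corpus generator uses the
#' same list as its filler vocabulary.
#'
#' @return A character vector of 100 lowercase words.
#' @export
#' @examples
#' head(common_word_list())
common_word_list <- function() .common_words
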