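# Built-in candidate lexicon for synthetic stimuli. Plain lowercase word
# forms; the generator only needs distinct strings, not real prose.
default_lexicon <- function() {
  c("winter", "snow", "cold", "ice", "frost", "wind", "white", "quiet",
    "trees", "fields", "morning", "light", "dark", "long", "night", "still",
    "river", "frozen", "sky", "gray", "clouds", "falls", "soft", "deep",
    "village", "roofs", "smoke", "warm", "fire", "home", "children", "play",
    "sleds", "hill", "laughter", "red", "cheeks", "mittens", "scarf", "boots",
    "path", "footsteps", "crunch", "silence", "stars", "clear", "moon",
    "shadow", "pine", "branches", "heavy", "rest", "slow", "breath", "air",
    "sharp", "glitter", "crystal", "lake", "black", "birds", "south", "few",
    "remain", "search", "seeds", "bare", "garden", "fence", "gate", "road",
    "distance", "bells", "evening", "lamp", "window", "glass", "pattern",
    "flower", "letter", "story", "music", "violin", "engine", "harbor",
    "spice", "desert", "volcano", "library", "pepper", "galaxy", "bicycle",
    "theory", "marble", "jungle", "anchor", "circus", "lantern", "meadow",
    "turbine", "origami", "glacier", "pyramid", "compass", "whisper",
    "thunder", "satellite", "orchid", "hammer", "canyon", "parrot", "comet",
    "bridge", "clock", "mirror", "ladder", "ocean", "candle", "forest",
    "puzzle", "rocket", "temple")
}

#' Configuration for the synthetic stimulus generator
#'
#' Defines a stimulus set with a controlled entropy gradient: `n_stimuli`
#' texts of exactly `words_per_text` tokens, where text k draws its tokens
#' from the first `vocabulary_sizes[k]` lexicon entries. Strictly increasing
#' vocabulary budgets produce strictly increasing cumulated entropy (the
#' generator verifies this and re-draws on the rare failure). Defaults mirror
#' the study design: five 100-word texts running from a highly repetitive
#' two-word text to one of maximal lexical variety; the geometric vocabulary
#' ladder yields an approximately evenly spaced entropy gradient.
#'
#' @param n_stimuli number of texts.
#' @param words_per_text tokens per text (must be >= max vocabulary budget).
#' @param vocabulary_sizes strictly increasing unique-word budgets, one per
#'   stimulus.
#' @param seed integer seed.
#' @param lexicon candidate word strings (>= max budget).
#' @return A `stimulus_gen_config` list.
#' @export
stimulus_gen_config <- function(n_stimuli = 5L,
                                words_per_text = 100L,
                                vocabulary_sizes = c(2L, 6L, 18L, 50L, 100L),
                                seed = 1L,
                                lexicon = default_lexicon()) {
  n_stimuli <- as.integer(n_stimuli)
  stopifnot(length(vocabulary_sizes) == n_stimuli,
            all(diff(vocabulary_sizes) > 0) || n_stimuli == 1L,
            max(vocabulary_sizes) <= length(lexicon),
            words_per_text >= max(vocabulary_sizes))
  structure(
    list(n_stimuli = n_stimuli,
         words_per_text = as.integer(words_per_text),
         vocabulary_sizes = as.integer(vocabulary_sizes),
         seed = as.integer(seed),
         lexicon = as.character(lexicon)),
    class = "stimulus_gen_config"
  )
}

#' Generate a synthetic stimulus set with an entropy gradient
#'
#' Text k is a seeded uniform draw of `words_per_text` tokens from its
#' vocabulary budget. The resulting cumulated entropies are checked to be
#' strictly increasing across stimuli; if a draw violates the gradient the
#' generator retries from a derived substream up to `max_retries` times,
#' then errors (infeasible budgets).
#'
#' @param config a [stimulus_gen_config()].
#' @param log_base entropy units for the attached profiles.
#' @param provider embedding provider for the profiles' semantic diversity.
#' @param max_retries bounded number of seeded re-draws.
#' @return List: `stimuli` (text_stimulus list), `profiles`
#'   (complexity_profile list), `config`.
#' @export
generate_stimulus_set <- function(config = stimulus_gen_config(),
                                  log_base = "e",
                                  provider = stub_embedding(),
                                  max_retries = 10L) {
  for (attempt in 0:max_retries) {
    seed_k <- substream_seed(config$seed, paste0("stimuli/", attempt))
    stimuli <- with_seed(seed_k, {
      lapply(seq_len(config$n_stimuli), function(k) {
        vocab <- config$lexicon[seq_len(config$vocabulary_sizes[k])]
        tokens <- sample(vocab, config$words_per_text, replace = TRUE)
        new_text_stimulus(sprintf("text_%d", k),
                          paste(tokens, collapse = " "),
                          tokens)
      })
    })
    h <- vapply(stimuli, cumulated_entropy, numeric(1), log_base = log_base)
    if (config$n_stimuli == 1L || all(diff(h) > 0)) {
      profiles <- complexity_profiles(stimuli, log_base = log_base,
                                      provider = provider)
      return(list(stimuli = stimuli, profiles = profiles, config = config))
    }
  }
  stop("could not realize a strictly increasing entropy gradient with the ",
       "given vocabulary budgets (", max_retries, " retries)", call. = FALSE)
}
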