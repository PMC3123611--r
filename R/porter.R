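# Porter stemming algorithm (Porter 1980), including the two standard
# departures adopted by the author's reference C implementation
# (step 2: bli -> ble rather than abli -> able, and the added logi -> log).
# Implemented here because no stemmer is otherwise available to the package;
# the suffix-stripping tables and conditions follow the published algorithm.

porter_is_cons <- function(chars) {
  n <- length(chars)
  res <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      res[i] <- FALSE
    } else if (ch == "y") {
      res[i] <- if (i == 1) TRUE else !res[i - 1]
    } else {
      res[i] <- TRUE
    }
  }
  res
}

# m() of Porter: number of VC sequences in the [C](VC)^m[V] decomposition.
porter_measure <- function(word) {
  if (!nzchar(word)) {
    return(0L)
  }
  runs <- rle(porter_is_cons(strsplit(word, "", fixed = TRUE)[[1]]))$values
  m <- 0L
  for (i in seq_along(runs)) {
    if (!runs[i] && i < length(runs) && runs[i + 1]) m <- m + 1L
  }
  m
}

porter_has_vowel <- function(word) {
  nzchar(word) && any(!porter_is_cons(strsplit(word, "", fixed = TRUE)[[1]]))
}

porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) {
    return(FALSE)
  }
  a <- substr(word, n - 1, n - 1)
  b <- substr(word, n, n)
  a == b && utils::tail(porter_is_cons(strsplit(word, "", fixed = TRUE)[[1]]), 1)
}

# *o condition: stem ends cvc where the final consonant is not w, x or y.
porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) {
    return(FALSE)
  }
  cons <- porter_is_cons(strsplit(word, "", fixed = TRUE)[[1]])
  last <- substr(word, n, n)
  cons[n - 2] && !cons[n - 1] && cons[n] && !(last %in% c("w", "x", "y"))
}

porter_ends <- function(word, suffix) {
  n <- nchar(word)
  ns <- nchar(suffix)
  n > ns && substr(word, n - ns + 1, n) == suffix
}

porter_chop <- function(word, k) substr(word, 1, nchar(word) - k)

# Replace the first (longest) matching suffix whose stem satisfies
# m(stem) > min_m; at most one rule fires, matching the reference switch.
porter_rule_table <- function(word, rules, min_m) {
  for (suf in names(rules)) {
    if (porter_ends(word, suf)) {
      stem <- porter_chop(word, nchar(suf))
      if (porter_measure(stem) > min_m) {
        return(paste0(stem, rules[[suf]]))
      }
      return(word)
    }
  }
  word
}

porter_step2_rules <- c(
  ational = "ate", ization = "ize", iveness = "ive", fulness = "ful",
  ousness = "ous", tional = "tion", biliti = "ble", ation = "ate",
  alism = "al", aliti = "al", ousli = "ous", entli = "ent", iviti = "ive",
  enci = "ence", anci = "ance", izer = "ize", alli = "al", ator = "ate",
  logi = "log", bli = "ble", eli = "e"
)

porter_step3_rules <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
  ness = "", ful = ""
)

porter_step4_suffixes <- c(
  "ement", "ance", "ence", "able", "ible", "ment", "ant", "ent", "ion",
  "ism", "ate", "iti", "ous", "ive", "ize", "ou", "al", "er", "ic"
)

porter_stem_word <- function(word) {
  if (nchar(word) <= 2 || grepl("[^a-z]", word)) {
    return(word)
  }

  # Step 1a
  if (porter_ends(word, "sses")) {
    word <- porter_chop(word, 2)
  } else if (porter_ends(word, "ies")) {
    word <- porter_chop(word, 2)
  } else if (porter_ends(word, "ss")) {
    # unchanged
  } else if (porter_ends(word, "s")) {
    word <- porter_chop(word, 1)
  }

  # Step 1b
  if (porter_ends(word, "eed")) {
    if (porter_measure(porter_chop(word, 3)) > 0) {
      word <- porter_chop(word, 1)
    }
  } else {
    stripped <- FALSE
    if (porter_ends(word, "ed") && porter_has_vowel(porter_chop(word, 2))) {
      word <- porter_chop(word, 2)
      stripped <- TRUE
    } else if (porter_ends(word, "ing") && porter_has_vowel(porter_chop(word, 3))) {
      word <- porter_chop(word, 3)
      stripped <- TRUE
    }
    if (stripped) {
      if (porter_ends(word, "at") || porter_ends(word, "bl") || porter_ends(word, "iz")) {
        word <- paste0(word, "e")
      } else if (porter_double_cons(word) &&
                 !(substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z"))) {
        word <- porter_chop(word, 1)
      } else if (porter_measure(word) == 1 && porter_cvc(word)) {
        word <- paste0(word, "e")
      }
    }
  }

  # Step 1c
  if (porter_ends(word, "y") && porter_has_vowel(porter_chop(word, 1))) {
    word <- paste0(porter_chop(word, 1), "i")
  }

  # Steps 2 and 3
  word <- porter_rule_table(word, as.list(porter_step2_rules), 0L)
  word <- porter_rule_table(word, as.list(porter_step3_rules), 0L)

  # Step 4
  for (suf in porter_step4_suffixes) {
    if (porter_ends(word, suf)) {
      stem <- porter_chop(word, nchar(suf))
      if (porter_measure(stem) > 1 &&
          (suf != "ion" || substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))) {
        word <- stem
      }
      break
    }
  }

  # Step 5a
  if (porter_ends(word, "e")) {
    stem <- porter_chop(word, 1)
    m <- porter_measure(stem)
    if (m > 1 || (m == 1 && !porter_cvc(stem))) {
      word <- stem
    }
  }

  # Step 5b
  if (porter_measure(word) > 1 && porter_double_cons(word) &&
      porter_ends(word, "l")) {
    word <- porter_chop(word, 1)
  }

  word
}

#' Porter stemmer
#'
#' Reduces English words to their Porter (1980) stems. Words of one or two
#' characters, and tokens containing anything other than lowercase ASCII
#' letters, are returned unchanged.
#'
#' @param words Character vector of lowercase tokens.
#' @return Character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("diseases", "relational", "temperature"))
#' @export
porter_stem <- function(words) {
  cache <- porter_cache()
  out <- character(length(words))
  for (i in seq_along(words)) {
    w <- words[i]
    if (!nzchar(w)) {
      next
    }
    hit <- cache[[w]]
    if (is.null(hit)) {
      hit <- porter_stem_word(w)
      cache[[w]] <- hit
    }
    out[i] <- hit
  }
  out
}

# Stems are pure functions of the word; memoize them for the session.
porter_cache <- local({
  env <- NULL
  function() {
    if (is.null(env)) {
      env <<- new.env(parent = emptyenv())
    }
    env
  }
})
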