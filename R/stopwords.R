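#' Packaged English stopword list
#'
#' The Snowball English stopword list, plus apostrophe-free variants of its
#' contractions (the tokenizer deletes punctuation characters, so "don't"
#' reaches the stopword filter as "dont"). Ambiguous de-apostrophized forms
#' that collide with content words (e.g. "well", "were", "id") are not added.
#'
#' @return character vector of lowercase stopwords.
#' @export
stopwords_en <- function() {
  base <- c(
    "i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his", "himself",
    "she", "her", "hers", "herself", "it", "its", "itself", "they", "them",
    "their", "theirs", "themselves", "what", "which", "who", "whom", "this",
    "that", "these", "those", "am", "is", "are", "was", "were", "be", "been",
    "being", "have", "has", "had", "having", "do", "does", "did", "doing",
    "would", "should", "could", "ought", "a", "an", "the", "and", "but",
    "if", "or", "because", "as", "until", "while", "of", "at", "by", "for",
    "with", "about", "against", "between", "into", "through", "during",
    "before", "after", "above", "below", "to", "from", "up", "down", "in",
    "out", "on", "off", "over", "under", "again", "further", "then", "once",
    "here", "there", "when", "where", "why", "how", "all", "any", "both",
    "each", "few", "more", "most", "other", "some", "such", "no", "nor",
    "not", "only", "own", "same", "so", "than", "too", "very"
  )
  contractions <- c(
    "im", "ive", "youre", "youve", "youll", "youd", "hes", "shes", "theyre",
    "theyve", "theyll", "theyd", "isnt", "arent", "wasnt", "werent", "hasnt",
    "havent", "hadnt", "doesnt", "dont", "didnt", "wont", "wouldnt", "shant",
    "shouldnt", "cant", "cannot", "couldnt", "mustnt", "thats", "whos",
    "whats", "heres", "theres", "whens", "wheres", "whys", "hows", "lets"
  )
  unique(c(base, contractions))
}
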