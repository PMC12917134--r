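# Bundled tagging resources. The tagger is lexicon-driven: a closed-class
# word list with Penn Treebank tags, an irregular-form table for lemmas, and
# documented suffix fallback rules for out-of-lexicon words. Feature values
# are tagger-dependent; this file IS the documentation of the tagging
# conventions used throughout the package.

# Subordinating conjunctions (PTB tags these IN; kept as an explicit word set
# so they can be separated from prepositions).
.sconj_words <- c(
  "because", "although", "though", "while", "whereas", "unless", "until",
  "if", "since", "once", "whenever", "wherever", "whether"
)

.tag_entries <- function() {
  tag <- function(words, t) stats::setNames(rep(t, length(words)), words)
  c(
    tag(c("the", "a", "an", "this", "that", "these", "those", "some", "any",
          "each", "every", "no", "another", "both", "all"), "DT"),
    tag(c("i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
          "us", "them", "himself", "herself", "itself", "themselves",
          "myself", "yourself"), "PRP"),
    tag(c("my", "your", "his", "its", "our", "their", "hers", "theirs"), "PRP$"),
    tag(c("who", "what", "whom"), "WP"),
    tag(c("in", "on", "at", "by", "with", "from", "of", "into", "onto",
          "over", "under", "near", "about", "through", "behind", "beside",
          "outside", "inside", "around", "across", "off", "up", "down",
          "above", "below", "between", "toward", "towards", "during",
          "against", "along", "past", "beneath", "upon", "within", "out"), "IN"),
    tag(.sconj_words, "IN"),
    tag("to", "TO"),
    tag(c("and", "or", "but", "nor", "yet", "so"), "CC"),
    tag(c("can", "could", "will", "would", "should", "may", "might", "must",
          "shall"), "MD"),
    tag(c("uh", "um", "er", "ah", "oh", "hmm", "mm", "huh", "erm"), "UH"),
    tag(c("is", "has", "does", "says", "goes", "wants", "seems", "looks",
          "runs", "falls", "stands", "sits", "plays", "washes", "reaches",
          "takes", "climbs", "flies", "reads", "eats", "drinks", "holds",
          "pours", "smiles", "waves", "walks", "tips", "spills", "steals",
          "hangs", "wobbles", "overflows", "dries", "carries", "watches",
          "points", "helps", "laughs", "sees"), "VBZ"),
    tag(c("are", "have", "do", "say", "want", "seem", "am"), "VBP"),
    tag(c("was", "were", "had", "did", "said", "went", "ran", "fell",
          "stood", "sat", "flew", "ate", "drank", "took", "saw", "held",
          "stole", "got", "came", "made", "washed", "dried", "reached",
          "climbed", "played", "looked", "poured", "smiled", "waved",
          "walked", "tipped", "spilled", "hung", "wobbled", "overflowed",
          "carried", "watched", "pointed", "helped", "laughed", "tried",
          "started", "stopped", "dropped", "noticed"), "VBD"),
    tag(c("be", "go", "run", "fall", "wash", "dry", "reach", "take",
          "climb", "stand", "play", "sit", "fly", "read", "eat", "drink",
          "look", "see", "hold", "pour", "smile", "wave", "walk", "tip",
          "spill", "steal", "hang", "wobble", "overflow", "carry", "watch",
          "point", "help", "laugh", "get", "come", "make", "try", "start",
          "stop", "drop", "notice"), "VB"),
    tag(c("been", "done", "gone", "taken", "seen", "fallen", "eaten",
          "given", "stolen", "broken", "forgotten"), "VBN"),
    tag(c("being", "having", "doing", "going", "running", "falling",
          "washing", "drying", "reaching", "taking", "climbing", "standing",
          "playing", "sitting", "flying", "reading", "eating", "drinking",
          "looking", "seeing", "holding", "pouring", "smiling", "waving",
          "walking", "tipping", "spilling", "stealing", "hanging",
          "wobbling", "overflowing", "carrying", "watching", "pointing",
          "helping", "laughing", "getting", "coming", "making", "trying",
          "starting", "stopping", "dropping", "noticing", "fishing",
          "sailing", "picnicking", "waving"), "VBG"),
    tag(c("very", "quite", "really", "also", "too", "then", "there", "here",
          "now", "again", "always", "often", "never", "maybe", "perhaps",
          "slowly", "quickly", "carefully", "quietly", "happily",
          "suddenly", "almost", "just", "still", "away", "back", "together",
          "outside", "nearby", "probably", "clearly", "busily"), "RB"),
    tag(c("big", "small", "little", "old", "young", "happy", "sad", "tall",
          "short", "long", "warm", "cold", "sunny", "busy", "quiet",
          "bright", "dark", "clean", "dirty", "full", "empty", "nice",
          "good", "bad", "red", "blue", "green", "white", "black", "wooden",
          "open", "high", "wet", "dry", "windy", "calm", "pleasant",
          "three-legged", "unsteady", "distracted", "careless"), "JJ"),
    tag(c("boy", "girl", "woman", "man", "mother", "father", "child",
          "lady", "sister", "brother", "kitchen", "cookie", "jar", "stool",
          "sink", "water", "floor", "window", "curtain", "dish", "plate",
          "cup", "counter", "cabinet", "garden", "tree", "dog", "cat",
          "house", "family", "picnic", "basket", "blanket", "sandwich",
          "lake", "boat", "kite", "flag", "book", "radio", "shoe", "fish",
          "bird", "table", "chair", "bread", "milk", "day", "week",
          "morning", "afternoon", "time", "thing", "hand", "apple", "sail",
          "shore", "bucket", "spade", "sand", "car", "park", "food",
          "drink", "glass", "wind", "grass", "tap", "cloth", "towel",
          "cupboard", "overflow", "mess", "puddle", "pail", "pier", "dock",
          "couple", "person", "people", "children", "feet", "foot", "side",
          "top", "edge", "background", "foreground", "scene", "picture",
          "weather", "moment", "home", "yard", "pond", "wagon", "doll",
          "hat", "ball", "string", "shirt", "dress", "apron", "sleeve",
          "arm", "leg", "head", "face", "plan", "trip", "walk", "visit",
          "story", "game"), "NN"),
    tag(c("one", "two", "three", "four", "five", "six", "seven", "eight",
          "nine", "ten"), "CD")
  )
}

.irregular_lemmas <- c(
  ran = "run", fell = "fall", stood = "stand", sat = "sit", flew = "fly",
  ate = "eat", drank = "drink", took = "take", saw = "see", held = "hold",
  stole = "steal", went = "go", was = "be", were = "be", is = "be",
  are = "be", am = "be", been = "be", being = "be", has = "have",
  had = "have", did = "do", does = "do", said = "say", got = "get",
  came = "come", made = "make", hung = "hang", children = "child",
  people = "person", feet = "foot", mice = "mouse", geese = "goose",
  wives = "wife", knives = "knife", wolves = "wolf", sheep = "sheep",
  taken = "take", seen = "see", fallen = "fall", eaten = "eat",
  given = "give", gone = "go", done = "do", stolen = "steal"
)

# Cached lexicon environment
.tag_env <- new.env(parent = emptyenv())

.tag_lexicon <- function() {
  if (is.null(.tag_env$lex)) .tag_env$lex <- .tag_entries()
  .tag_env$lex
}

#' English word list used by `words_not_in_dict_ratio`
#'
#' The bundled dictionary is the union of the tagger lexicon and the
#' irregular-form table; it can be extended via the `extra_words` argument of
#' [extract_linguistic_features()].
#' @return character vector of lowercase words.
#' @export
english_dictionary <- function() {
  sort(unique(c(names(.tag_lexicon()), names(.irregular_lemmas),
                unname(.irregular_lemmas))))
}
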