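# Closed-class word lists and small open-class lexicons driving the rule-based
# POS tagger and the effective-word filter.  Tags follow the Penn convention
# at a coarse granularity (DT, IN, CC, PRP, MD, TO, EX, RB, JJ, NN, NNS,
# VB, VBP, VBZ, VBD, VBG, VBN, CD).

.determiners <- c(
  "the", "a", "an", "this", "that", "these", "those", "no", "some", "any",
  "each", "every", "either", "neither", "all", "both", "another", "such"
)

.prepositions <- c(
  "of", "in", "on", "at", "by", "for", "with", "from", "to", "into", "onto",
  "over", "under", "between", "among", "during", "without", "within",
  "about", "against", "after", "before", "through", "as", "than", "around",
  "because", "if", "while", "since", "although", "though", "whether", "per",
  "across", "toward", "towards", "upon", "via", "despite", "until"
)

.conjunctions <- c("and", "or", "but", "nor", "yet", "so", "plus")

.pronouns <- c(
  "i", "you", "he", "she", "it", "we", "they", "me", "him", "her", "us",
  "them", "my", "your", "his", "its", "our", "their", "mine", "yours",
  "hers", "ours", "theirs", "who", "whom", "whose", "which", "what", "there",
  "himself", "herself", "itself", "themselves", "one", "something",
  "anything", "nothing", "everything", "someone", "anyone", "everyone"
)

.modals <- c("can", "could", "will", "would", "shall", "should", "may",
             "might", "must")

# Auxiliary forms with their lemma and tag.
.aux_table <- data.frame(
  word  = c("be", "am", "is", "are", "was", "were", "been", "being",
            "have", "has", "had", "having", "do", "does", "did", "doing",
            "done"),
  lemma = c("be", "be", "be", "be", "be", "be", "be", "be",
            "have", "have", "have", "have", "do", "do", "do", "do", "do"),
  tag   = c("VB", "VBP", "VBZ", "VBP", "VBD", "VBD", "VBN", "VBG",
            "VBP", "VBZ", "VBD", "VBG", "VBP", "VBZ", "VBD", "VBG", "VBN"),
  stringsAsFactors = FALSE
)

# Negation triggers (NegEx-style pre-/pseudo-trigger subset sufficient for
# sentence-level polarity).
.negation_triggers <- c(
  "no", "not", "neither", "nor", "never", "without", "n't", "cannot",
  "none", "nobody", "nothing", "denies", "denied", "deny", "absence",
  "negative", "unremarkable", "free"
)
.negation_pseudo <- c("no increase", "no change", "not only", "no further",
                      "without difficulty", "not necessarily")

# Base-form verb lexicon (open class).  Inflections are recognised by
# morphology against these bases.
.verb_bases <- c(
  "report", "observe", "play", "stand", "run", "walk", "eat", "look", "cut",
  "slice", "take", "land", "sit", "bark", "jump", "ride", "wear", "hold",
  "throw", "catch", "climb", "swim", "sing", "dance", "cook", "wash",
  "drive", "read", "write", "open", "close", "move", "treat", "improve",
  "reduce", "increase", "decrease", "show", "find", "measure", "compare",
  "receive", "give", "use", "perform", "occur", "require", "include",
  "assess", "evaluate", "randomise", "randomize", "chase", "watch", "carry",
  "kick", "push", "pull", "lift", "see", "say", "make", "go", "come",
  "sleep", "smile", "laugh", "cry", "talk", "speak", "remain", "appear",
  "seem", "follow", "cause", "affect", "prevent", "detect", "examine",
  "study", "test", "note", "record", "describe"
)

# Irregular verb inflections -> (lemma, tag)
.irregular_verbs <- data.frame(
  word  = c("ran", "ate", "sat", "took", "taken", "wore", "worn", "held",
            "threw", "thrown", "swam", "swum", "sang", "sung", "drove",
            "driven", "found", "gave", "given", "saw", "seen", "said",
            "made", "went", "gone", "came", "slept", "spoke", "spoken",
            "cut", "read", "wrote", "written"),
  lemma = c("run", "eat", "sit", "take", "take", "wear", "wear", "hold",
            "throw", "throw", "swim", "swim", "sing", "sing", "drive",
            "drive", "find", "give", "give", "see", "see", "say",
            "make", "go", "go", "come", "sleep", "speak", "speak",
            "cut", "read", "write", "write"),
  tag   = c("VBD", "VBD", "VBD", "VBD", "VBN", "VBD", "VBN", "VBD",
            "VBD", "VBN", "VBD", "VBN", "VBD", "VBN", "VBD",
            "VBN", "VBD", "VBD", "VBN", "VBD", "VBN", "VBD",
            "VBD", "VBD", "VBN", "VBD", "VBD", "VBD", "VBN",
            "VBD", "VBD", "VBD", "VBN"),
  stringsAsFactors = FALSE
)

# Noun lexicon: words that default rules could mis-tag (e.g. verb-homograph
# "wound") plus common domain and fixture nouns.
.noun_bases <- c(
  "wound", "group", "yard", "man", "woman", "kid", "child", "dog", "cat",
  "event", "retention", "disturbance", "infection", "patient", "outcome",
  "intervention", "population", "background", "study", "design", "trial",
  "treatment", "therapy", "surgery", "pain", "score", "effect", "result",
  "airplane", "plane", "store", "counter", "vegetable", "ball", "tree",
  "house", "street", "park", "river", "mountain", "bird", "horse", "boy",
  "girl", "person", "doctor", "nurse", "drug", "dose", "risk", "rate",
  "review", "evidence", "sentence", "statement"
)
.irregular_nouns <- data.frame(
  word  = c("men", "women", "children", "people", "feet", "teeth", "mice"),
  lemma = c("man", "woman", "child", "person", "foot", "tooth", "mouse"),
  stringsAsFactors = FALSE
)

# Adjective lexicon for words no suffix rule covers.
.adjective_bases <- c(
  "adverse", "old", "young", "big", "small", "large", "new", "good", "bad",
  "high", "low", "same", "different", "several", "many", "few", "more",
  "most", "less", "least", "clinical", "relevant", "severe", "mild",
  "acute", "chronic", "significant", "black", "white", "brown", "red",
  "blue", "green", "happy", "sad", "main", "common", "rare", "similar"
)

.adjective_suffixes <- c("ive", "ous", "ary", "ory", "ant", "ent", "al",
                         "ful", "less", "ic", "able", "ible")
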