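# Deterministic offline mini-lexicon: a small taxonomy with IC values and
# lexicographer-style categories, a frame lexicon, and a distributional term
# space.  It emulates the structure of the real knowledge resources so that
# every semantic feature can be exercised (and hand-checked) offline; it is
# synthetic and makes no claim about real lexical coverage.

.mini_taxonomy_skeleton <- function() {
  # root / mid-level categories / leaf concepts.  Categories follow the
  # lexicographer-file naming style.
  mid <- data.frame(
    synset_id = c("animal.n.01", "person.n.01", "artifact.n.01",
                  "event.n.01", "state.n.01", "act.n.01", "plant.n.01"),
    category  = c("noun.animal", "noun.person", "noun.artifact",
                  "noun.event", "noun.state", "noun.act", "noun.plant"),
    gloss = c("living creature organism", "human being individual",
              "man made object thing", "happening occurrence phenomenon",
              "condition situation way", "deed action doing",
              "living organism flora"),
    stringsAsFactors = FALSE
  )
  leaves <- data.frame(
    synset_id = c("dog.n.01", "cat.n.01", "horse.n.01", "bird.n.01",
                  "mouse.n.01",
                  "man.n.01", "woman.n.01", "kid.n.01", "doctor.n.01",
                  "nurse.n.01",
                  "ball.n.01", "house.n.01", "store.n.01", "vegetable.n.01",
                  "mouse.n.02", "yard.n.01",
                  "event.n.02", "infection.n.01", "disturbance.n.01",
                  "outcome.n.01",
                  "pain.n.01", "retention.n.01",
                  "treatment.n.01", "surgery.n.01", "intervention.n.01",
                  "game.n.01",
                  "tree.n.01", "grass.n.01"),
    parent = c(rep("animal.n.01", 5), rep("person.n.01", 5),
               rep("artifact.n.01", 6), rep("event.n.01", 4),
               rep("state.n.01", 2), rep("act.n.01", 4),
               rep("plant.n.01", 2)),
    gloss = c("domestic canine animal kept pet", "domestic feline animal pet",
              "large hoofed animal ridden", "feathered animal that flies",
              "small rodent animal",
              "adult male person", "adult female person",
              "young person child", "person who treats patients",
              "person who cares for patients",
              "round object used in games", "building where people live",
              "building where goods are sold", "edible plant part food",
              "hand device for computer", "ground area near house",
              "phenomenon that follows and is caused by some previous phenomenon",
              "invasion of the body by pathogens",
              "disruption of a normal state", "final result of a process",
              "unpleasant bodily sensation", "keeping something inside",
              "care given to a patient", "medical operation on a patient",
              "deliberate act to change a course", "contest with rules played",
              "tall woody plant", "green ground plant"),
    stringsAsFactors = FALSE
  )
  list(mid = mid, leaves = leaves)
}

.mini_senses <- function() {
  # lemma -> synset mapping with sense ranks; a few ambiguous lemmas give
  # the Lesk disambiguator real work ("mouse": animal vs. pointing device).
  data.frame(
    lemma = c("dog", "cat", "horse", "bird", "mouse", "mouse",
              "man", "woman", "kid", "child", "doctor", "nurse",
              "ball", "house", "store", "vegetable", "yard",
              "event", "event", "infection", "disturbance", "outcome",
              "pain", "retention", "treatment", "surgery", "intervention",
              "game", "tree", "grass", "animal", "person"),
    pos = "n",
    rank = c(1L, 1L, 1L, 1L, 1L, 2L,
             1L, 1L, 1L, 1L, 1L, 1L,
             1L, 1L, 1L, 1L, 1L,
             1L, 2L, 1L, 1L, 1L,
             1L, 1L, 1L, 1L, 1L,
             1L, 1L, 1L, 1L, 1L),
    synset_id = c("dog.n.01", "cat.n.01", "horse.n.01", "bird.n.01",
                  "mouse.n.01", "mouse.n.02",
                  "man.n.01", "woman.n.01", "kid.n.01", "kid.n.01",
                  "doctor.n.01", "nurse.n.01",
                  "ball.n.01", "house.n.01", "store.n.01", "vegetable.n.01",
                  "yard.n.01",
                  "game.n.01", "event.n.02", "infection.n.01",
                  "disturbance.n.01", "outcome.n.01",
                  "pain.n.01", "retention.n.01", "treatment.n.01",
                  "surgery.n.01", "intervention.n.01",
                  "game.n.01", "tree.n.01", "grass.n.01",
                  "animal.n.01", "person.n.01"),
    stringsAsFactors = FALSE
  )
}

.mini_frames <- function() {
  data.frame(
    lemma = c("report", "say", "describe", "observe", "look", "watch", "see",
              "run", "walk", "jump", "ride", "stand", "sit",
              "eat", "play", "treat", "cut", "slice", "give", "take", "be",
              "infection", "disturbance", "event", "outcome", "treatment",
              "surgery", "pain"),
    frame_id = c("Statement", "Statement", "Statement",
                 "Perception", "Perception", "Perception", "Perception",
                 "Motion", "Motion", "Motion", "Motion", "Posture", "Posture",
                 "Ingestion", "Competition", "Cure", "Cutting", "Cutting",
                 "Giving", "Taking", "State",
                 "Medical_condition", "Medical_condition", "Event",
                 "Event", "Cure", "Cure", "Perception_body"),
    stringsAsFactors = FALSE
  )
}

#' Build the deterministic offline mini-lexicon
#'
#' Generates the three knowledge backends from a fixed symbolic skeleton
#' plus seed-dependent numeric content: a 3-level taxonomy (36 synsets, 8
#' lexicographer categories) with IC values that grow from root to leaf, a
#' frame lexicon (21 verb and 7 noun lemmas over 11 frames), and a
#' distributional space (48 terms, dimension 8) whose vectors cluster by
#' taxonomy branch so that nearest-neighbour sets are semantically coherent.
#' Identical seeds give identical bundles.
#'
#' @param seed integer seed controlling IC jitter and vector noise.
#' @param dim term-vector dimension (default 8).
#' @return a `backend_bundle`.
#' @examples
#' bk <- build_mini_lexicon(1)
#' lin_similarity("dog.n.01", "cat.n.01", bk$taxonomy)
#' @export
build_mini_lexicon <- function(seed = 1L, dim = 8L) {
  sk <- .mini_taxonomy_skeleton()
  with_seed(derive_seed(seed, "mini-lexicon"), {
    root <- data.frame(synset_id = "entity.n.01", parent = NA_character_,
                       depth = 1L, ic = 0,
                       category = "noun.tops", gloss = "that which exists",
                       stringsAsFactors = FALSE)
    mid <- data.frame(synset_id = sk$mid$synset_id, parent = "entity.n.01",
                      depth = 2L,
                      ic = round(stats::runif(nrow(sk$mid), 1, 3), 3),
                      category = sk$mid$category, gloss = sk$mid$gloss,
                      stringsAsFactors = FALSE)
    pid <- match(sk$leaves$parent, mid$synset_id)
    leaves <- data.frame(
      synset_id = sk$leaves$synset_id, parent = sk$leaves$parent,
      depth = 3L,
      ic = round(mid$ic[pid] + stats::runif(nrow(sk$leaves), 1, 3), 3),
      category = mid$category[pid], gloss = sk$leaves$gloss,
      stringsAsFactors = FALSE
    )
    syn <- rbind(root, mid, leaves)
    tax <- taxonomy_backend(syn, .mini_senses())
    fr <- frame_backend(.mini_frames())

    # clustered term vectors: one prototype per taxonomy branch (verbs get a
    # frame-based prototype), plus per-term noise
    branch_of <- c(stats::setNames(sk$leaves$parent, sub("\\.n\\..*", "", sk$leaves$synset_id)))
    verb_terms <- unique(.mini_frames()$lemma)
    frame_of <- stats::setNames(.mini_frames()$frame_id[match(verb_terms, .mini_frames()$lemma)], verb_terms)
    groups <- unique(c(branch_of, frame_of))
    protos <- matrix(stats::rnorm(length(groups) * dim, sd = 1),
                     nrow = length(groups), dimnames = list(groups, NULL))
    terms <- unique(c(names(branch_of), verb_terms))
    vecs <- t(vapply(terms, function(t) {
      g <- if (t %in% names(branch_of)) branch_of[[t]] else frame_of[[t]]
      protos[g, ] + stats::rnorm(dim, sd = 0.3)
    }, numeric(dim)))
    rownames(vecs) <- terms
    backend_bundle(tax, fr, dist_backend(round(vecs, 4)))
  })
}
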