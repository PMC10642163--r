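# Condition names and labelled-corpus frequencies used as the default
# class-imbalance profile of the synthetic generator (ENT specialty,
# adult and paediatric). Zero-frequency conditions stay in the catalog
# but are never sampled.
.ent_adult_freq <- c(
  "Allergic rhinitis/nasal congestion/obstruction" = 0,
  "chronic ear disease" = 82,
  "dizziness/vertigo" = 37,
  "dysphagia" = 103,
  "dysphonia" = 124,
  "ear drum perforation" = 20,
  "epistaxis (recurrent)" = 31,
  "facial nerve palsy" = 2,
  "head and neck mass" = 100,
  "hearing loss" = 180,
  "nasal fracture (acute)" = 28,
  "obstructive sleep apnoea" = 42,
  "oropharyngeal lesions" = 47,
  "primary parathyroid adenoma" = 3,
  "rhinosinusitis (chronic/recurrent)" = 214,
  "salivary tumour" = 13,
  "sialolithiasis (salivary stones)" = 10,
  "thyroid mass" = 27,
  "tinnitus" = 45,
  "tonsillitis (recurrent) or tonsillar enlargement" = 127
)

.ent_paediatric_freq <- c(
  "dysphonia/hoarseness" = 4,
  "epistaxis (recurrent)" = 5,
  "hearing loss" = 24,
  "Nasal allergic rhinitis/congestion/obstruction" = 0,
  "Nasal fracture (acute)" = 0,
  "Neck mass" = 0,
  "otitis externa" = 3,
  "Otitis media-acute otitis media with or without perforation (AOMwiP/AOMwoP)" = 0,
  "Otitis media-with effusion (OME or glue ear)" = 0,
  "perforated eardrum/chronic suppurative otitis media (CSOM)" = 5,
  "sleep disordered breathing/obstructive sleep apnoea" = 36,
  "stridor" = 3,
  "tonsillitis (recurrent)" = 50
)

#' Class-imbalance profiles for the synthetic generator
#'
#' `"table3"` reproduces the labelled-corpus ENT condition frequencies
#' (for example adult chronic rhinosinusitis 214, hearing loss 180,
#' facial nerve palsy 2; paediatric neck mass 0), normalised per age
#' group; zero-frequency conditions get weight 0 but remain in the
#' catalog, so they can be predicted yet are never sampled. `"uniform"`
#' weights every condition equally. `"custom"` validates and normalises
#' user weights.
#'
#' @param name `"table3"`, `"uniform"` or `"custom"`.
#' @param age_group `"adult"` or `"paediatric"`.
#' @param n_cpcs Number of conditions (for `"uniform"`).
#' @param custom Named non-negative weights summing to 1 (for
#'   `"custom"`).
#' @return Named numeric weight vector summing to 1.
#' @export
imbalance_profile <- function(name = c("table3", "uniform", "custom"),
                              age_group = c("adult", "paediatric"),
                              n_cpcs = NULL, custom = NULL) {
  name <- match.arg(name)
  age_group <- match.arg(age_group)
  if (name == "table3") {
    freq <- if (age_group == "adult") .ent_adult_freq else
      .ent_paediatric_freq
    return(freq / sum(freq))
  }
  if (name == "uniform") {
    stopifnot(!is.null(n_cpcs), n_cpcs >= 1L)
    return(setNames(rep(1 / n_cpcs, n_cpcs), NULL))
  }
  stopifnot(!is.null(custom), is.numeric(custom), all(custom >= 0))
  if (abs(sum(custom) - 1) > 1e-8) {
    stop("custom class weights must sum to 1")
  }
  custom
}

#' Synthetic corpus generator configuration
#'
#' Fixes every statistical property of the generated data: catalog
#' sizes (20 adult, 13 paediatric conditions), the labelled fraction
#' (0.097 of referrals carry a CPC label), the class-imbalance profile,
#' referral length, the share of referral terms drawn from the true
#' condition's vocabulary (`signal_fraction`), the per-term typo rate,
#' and the probability that the historical category is re-drawn
#' uniformly at random rather than copied from the CPC-implied category
#' (`historical_noise`; the probability that the historical label
#' actually differs is therefore `historical_noise * 2/3`).
#'
#' @param seed Integer seed (below 2^31 - 16); all generator randomness
#'   derives from it.
#' @param n_referrals Number of referrals to generate.
#' @param n_adult_cpcs,n_paediatric_cpcs Catalog sizes (defaults 20 and
#'   13).
#' @param labeled_fraction Probability a referral carries its CPC label,
#'   default 0.097.
#' @param profile Class-imbalance profile name, default `"table3"`
#'   (requires the default catalog sizes); see [imbalance_profile()].
#' @param class_weights Optional custom per-age-group weights, a list
#'   with elements `adult` and `paediatric`.
#' @param adult_fraction Probability a referral is adult, default 0.673
#'   (the adult share of the real corpus).
#' @param terms_range Integer range of terms per referral, default
#'   `c(6, 14)`.
#' @param signal_fraction Share of terms drawn from the true
#'   condition/category vocabulary, default 0.6; the rest is shared
#'   background vocabulary.
#' @param typo_rate Probability each signal term receives one random
#'   single-character edit, default 0.05.
#' @param historical_noise Probability the historical category is
#'   re-drawn uniformly from {1, 2, 3}, default 0.3.
#' @param core_terms_per_cpc Core vocabulary size per condition,
#'   default 12 (split 4/4/4 across categories).
#' @param background_vocab Size of the shared background vocabulary,
#'   default 40.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_referrals = 1000L,
                             n_adult_cpcs = 20L, n_paediatric_cpcs = 13L,
                             labeled_fraction = 0.097,
                             profile = "table3", class_weights = NULL,
                             adult_fraction = 0.673,
                             terms_range = c(6L, 14L),
                             signal_fraction = 0.6, typo_rate = 0.05,
                             historical_noise = 0.3,
                             core_terms_per_cpc = 12L,
                             background_vocab = 40L) {
  stopifnot(n_referrals >= 0L, n_adult_cpcs >= 2L, n_paediatric_cpcs >= 2L,
            labeled_fraction >= 0, labeled_fraction <= 1,
            adult_fraction >= 0, adult_fraction <= 1,
            signal_fraction >= 0, signal_fraction <= 1,
            typo_rate >= 0, typo_rate <= 1,
            historical_noise >= 0, historical_noise <= 1,
            length(terms_range) == 2L, terms_range[1] >= 1L,
            terms_range[2] >= terms_range[1],
            core_terms_per_cpc >= 6L, background_vocab >= 1L,
            abs(seed) < 2^31 - 16)
  if (profile == "table3" &&
      (n_adult_cpcs != 20L || n_paediatric_cpcs != 13L)) {
    stop("the table3 profile requires 20 adult and 13 paediatric CPCs; ",
         "use profile 'uniform' or 'custom' with other catalog sizes")
  }
  if (!is.null(class_weights)) {
    stopifnot(is.list(class_weights),
              all(c("adult", "paediatric") %in% names(class_weights)))
    for (ag in .age_groups) {
      if (abs(sum(class_weights[[ag]]) - 1) > 1e-8) {
        stop("class weights for ", ag, " must sum to 1")
      }
    }
    profile <- "custom"
  }
  structure(
    list(seed = as.integer(seed), n_referrals = as.integer(n_referrals),
         n_adult_cpcs = as.integer(n_adult_cpcs),
         n_paediatric_cpcs = as.integer(n_paediatric_cpcs),
         labeled_fraction = labeled_fraction, profile = profile,
         class_weights = class_weights, adult_fraction = adult_fraction,
         terms_range = as.integer(terms_range),
         signal_fraction = signal_fraction, typo_rate = typo_rate,
         historical_noise = historical_noise,
         core_terms_per_cpc = as.integer(core_terms_per_cpc),
         background_vocab = as.integer(background_vocab)),
    class = "generator_config"
  )
}

.gen_consonants <- c("b", "d", "f", "g", "h", "j", "k", "l", "m", "n",
                     "p", "r", "t", "v", "z")
.gen_vowels <- c("a", "e", "i", "o", "u")

# pronounceable CV-syllable word ending in a consonant; engineered to be
# (near-)invariant under stemming
.make_word <- function() {
  k <- sample(2:3, 1L)
  syll <- vapply(seq_len(k), function(i) {
    paste0(sample(.gen_consonants, 1L), sample(.gen_vowels, 1L))
  }, character(1))
  paste0(paste(syll, collapse = ""), sample(.gen_consonants, 1L))
}

# stem to a fixpoint so generated vocabulary is stable under the
# preprocessing pipeline
.stem_fix <- function(words) {
  for (i in 1:3) {
    s <- porter_stem(words)
    if (identical(s, words)) break
    words <- s
  }
  words
}

.term_pool <- function(n) {
  seen <- character(0)
  while (length(seen) < n) {
    w <- .stem_fix(replicate(max(n, 50L), .make_word()))
    seen <- unique(c(seen, w))
  }
  seen[seq_len(n)]
}

# one random single-character edit guaranteed to change the word
.apply_typo <- function(word) {
  n <- nchar(word)
  op <- if (n <= 1L) sample(c("sub", "ins"), 1L) else
    sample(c("sub", "ins", "del"), 1L)
  letters_pool <- c(.gen_consonants, .gen_vowels)
  if (op == "sub") {
    i <- sample.int(n, 1L)
    old <- substr(word, i, i)
    new <- sample(setdiff(letters_pool, old), 1L)
    return(paste0(substr(word, 1L, i - 1L), new, substr(word, i + 1L, n)))
  }
  if (op == "ins") {
    i <- sample.int(n + 1L, 1L) - 1L
    return(paste0(substr(word, 1L, i), sample(letters_pool, 1L),
                  substr(word, i + 1L, n)))
  }
  i <- sample.int(n, 1L)
  paste0(substr(word, 1L, i - 1L), substr(word, i + 1L, n))
}

.slug <- function(x) {
  s <- gsub("[^a-z0-9]+", "-", tolower(x))
  gsub("^-|-$", "", s)
}

#' Generate a synthetic CPC catalog
#'
#' Builds a catalog whose structure mirrors real CPC documents: each
#' condition receives a disjoint core vocabulary (split across the three
#' urgency categories), the `keywords` representation holds the core
#' terms, `medical_terms` adds one morphological variant per core term
#' (emulating surface variation such as "blocked" / "blockage"), and
#' `criteria_words` further adds shared filler words (emulating the
#' residual noise of full criteria text). With the default table3
#' profile the conditions carry the real ENT condition names and the
#' adult head and neck mass condition is marked `fixed_category = 1`.
#' Deterministic given the configuration seed.
#'
#' @param config A [generator_config()].
#' @return List with `catalog` (a [cpc_catalog()]), `vocab` (per-CPC
#'   core/variant vocabulary map), `background` (shared vocabulary) and
#'   `weights` (per-age-group sampling weights).
#' @export
generate_catalog <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_cpcs <- c(adult = config$n_adult_cpcs,
              paediatric = config$n_paediatric_cpcs)
  core_n <- config$core_terms_per_cpc
  pool <- .term_pool(sum(n_cpcs) * core_n + config$background_vocab)
  background <- pool[seq_len(config$background_vocab)]
  pool <- pool[-seq_len(config$background_vocab)]
  suffixes <- c("um", "ik", "ox")
  entries <- list()
  vocab <- list()
  weights <- list()
  ptr <- 0L
  for (ag in .age_groups) {
    k <- n_cpcs[[ag]]
    cond_names <- if (config$profile == "table3") {
      names(if (ag == "adult") .ent_adult_freq else .ent_paediatric_freq)
    } else {
      paste0(ag, " condition ", sprintf("%02d", seq_len(k)))
    }
    weights[[ag]] <- if (config$profile == "custom") {
      config$class_weights[[ag]]
    } else if (config$profile == "table3") {
      imbalance_profile("table3", ag)
    } else {
      imbalance_profile("uniform", ag, n_cpcs = k)
    }
    ids <- paste0(substr(ag, 1L, 2L), "-", .slug(cond_names))
    names(weights[[ag]]) <- ids
    per_cat <- core_n %/% 3L
    for (j in seq_len(k)) {
      core <- pool[ptr + seq_len(core_n)]
      ptr <- ptr + core_n
      variants <- .stem_fix(paste0(core, sample(suffixes, core_n,
                                                replace = TRUE)))
      cat_idx <- split(seq_len(core_n),
                       rep(1:3, c(per_cat, per_cat,
                                  core_n - 2L * per_cat)))
      kw <- lapply(cat_idx, function(ii) core[ii])
      mt <- lapply(1:3, function(c3) c(kw[[c3]],
                                       variants[cat_idx[[c3]]]))
      cw <- lapply(1:3, function(c3) {
        c(mt[[c3]], sample(background, 3L))
      })
      names(kw) <- names(mt) <- names(cw) <- as.character(1:3)
      fixed <- NULL
      if (config$profile == "table3" && ag == "adult" &&
          cond_names[j] == "head and neck mass") {
        fixed <- 1L
      }
      entries[[length(entries) + 1L]] <- cpc_definition(
        cpc_id = ids[j], age_group = ag,
        condition_name = cond_names[j],
        representations = list(criteria_words = cw, medical_terms = mt,
                               keywords = kw),
        fixed_category = fixed
      )
      vocab[[ids[j]]] <- list(core = core, variants = variants,
                              categories = cat_idx)
    }
  }
  list(catalog = cpc_catalog(entries), vocab = vocab,
       background = background, weights = weights)
}

#' Generate synthetic referrals with ground truth
#'
#' Samples each referral's age group, true condition (by the class
#' weights), true category (the fixed category when the condition
#' mandates one, else uniform), and terms: `signal_fraction` of the
#' terms come from the true condition's vocabulary — the true category's
#' keyword unit (triple weight) plus the condition's morphological
#' variants — and the rest from the shared background vocabulary; each
#' signal term is corrupted with one random
#' single-character edit with probability `typo_rate`. A fraction
#' `labeled_fraction` of referrals carry the condition name as their
#' raw CPC label (lodged via the electronic channel); the historical
#' category is re-drawn uniformly with probability `historical_noise`.
#' Dates of birth and submission are consistent with the age group.
#' Entity records (confidence 1.0) are emitted for every term so both
#' ingestion paths can be exercised. Deterministic given the
#' configuration seed.
#'
#' @param generated A [generate_catalog()] result.
#' @param config The same [generator_config()].
#' @return List with `referrals` (data.frame: `referral_id`, `text`,
#'   `dob`, `submitted`, `cpc_label`, `category`, `lodgment`),
#'   `entities` (named list of entity data.frames), `terms` (named list
#'   of the generated token vectors) and `truth` (data.frame:
#'   `referral_id`, `age_group`, `true_cpc`, `true_category`).
#' @export
generate_referrals <- function(generated, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"),
            is.list(generated), !is.null(generated$catalog))
  if (config$n_referrals < 1L) {
    stop("n_referrals must be at least 1")
  }
  set.seed(config$seed + 1L)
  catalog <- generated$catalog
  vocab <- generated$vocab
  n <- config$n_referrals
  ids <- sprintf("R%06d", seq_len(n))
  ag <- ifelse(runif(n) < config$adult_fraction, "adult", "paediatric")
  referrals <- vector("list", n)
  entities <- vector("list", n)
  terms_out <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    w <- generated$weights[[ag[i]]]
    cpc_id <- sample(names(w), 1L, prob = w)
    def <- .get_cpc(catalog, cpc_id, ag[i])
    v <- vocab[[cpc_id]]
    true_cat <- if (!is.null(def$fixed_category)) def$fixed_category else
      sample(1:3, 1L)
    unit_idx <- v$categories[[true_cat]]
    nt <- sample(config$terms_range[1]:config$terms_range[2], 1L)
    ns <- round(config$signal_fraction * nt)
    # category-bearing signal: the true category's keyword unit (at
    # least one token whenever any signal is drawn); condition-bearing
    # signal: the condition's morphological variants, drawn
    # condition-wide (variant usage is not category-specific in real
    # text)
    nb <- ceiling(ns / 2)
    signal <- c(
      if (nb > 0L) sample(v$core[unit_idx], nb, replace = TRUE) else
        character(0),
      if (ns - nb > 0L) sample(v$variants, ns - nb, replace = TRUE) else
        character(0)
    )
    if (config$typo_rate > 0 && length(signal)) {
      hit <- runif(length(signal)) < config$typo_rate
      signal[hit] <- vapply(signal[hit], .apply_typo, character(1))
    }
    noise <- if (nt - ns > 0L) {
      sample(generated$background, nt - ns, replace = TRUE)
    } else {
      character(0)
    }
    terms <- sample(c(signal, noise))
    labeled <- runif(1) < config$labeled_fraction
    hist_cat <- if (runif(1) < config$historical_noise) sample(1:3, 1L) else
      true_cat
    submitted <- as.Date("2019-01-01") + sample(0:1399, 1L)
    age <- if (ag[i] == "adult") sample(17:89, 1L) else sample(1:14, 1L)
    dob <- submitted - round(age * 365.25) - sample(0:300, 1L)
    referrals[[i]] <- data.frame(
      referral_id = ids[i],
      text = paste(terms, collapse = " "),
      dob = dob, submitted = submitted,
      cpc_label = if (labeled) def$condition_name else NA_character_,
      category = hist_cat,
      lodgment = if (labeled) "GPSR" else
        sample(c("GPSR", "email", "fax", "manual", "STS"), 1L,
               prob = c(0.12, 0.37, 0.47, 0.035, 0.005)),
      stringsAsFactors = FALSE
    )
    entities[[i]] <- data.frame(
      text = terms, category = "Medical_Condition", type = "DX_Name",
      score = 1.0, stringsAsFactors = FALSE
    )
    terms_out[[i]] <- terms
    truth[[i]] <- data.frame(referral_id = ids[i], age_group = ag[i],
                             true_cpc = cpc_id, true_category = true_cat,
                             stringsAsFactors = FALSE)
  }
  names(entities) <- ids
  names(terms_out) <- ids
  list(referrals = do.call(rbind, referrals),
       entities = entities, terms = terms_out,
       truth = do.call(rbind, truth))
}

#' Generate a complete synthetic corpus
#'
#' Convenience wrapper: [generate_catalog()] followed by
#' [generate_referrals()].
#'
#' @param config A [generator_config()].
#' @return List combining both results: `catalog`, `vocab`,
#'   `background`, `weights`, `referrals`, `entities`, `terms`,
#'   `truth`.
#' @export
generate_corpus <- function(config = generator_config()) {
  gen <- generate_catalog(config)
  c(gen, generate_referrals(gen, config))
}

#' Write a synthetic corpus to disk
#'
#' Writes `referrals.csv`, `entities.json` (keyed by referral id, NER
#' response shape), `catalog.json` and `truth.csv` under `dir`.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(referrals = file.path(dir, "referrals.csv"),
             entities = file.path(dir, "entities.json"),
             catalog = file.path(dir, "catalog.json"),
             truth = file.path(dir, "truth.csv"))
  write.csv(corpus$referrals, paths[["referrals"]], row.names = FALSE)
  ent <- lapply(corpus$entities, function(df) {
    list(Entities = lapply(seq_len(nrow(df)), function(r) {
      list(Text = jsonlite::unbox(df$text[r]),
           Category = jsonlite::unbox(df$category[r]),
           Type = jsonlite::unbox(df$type[r]),
           Score = jsonlite::unbox(df$score[r]))
    }))
  })
  jsonlite::write_json(ent, paths[["entities"]], digits = NA)
  write_catalog(corpus$catalog, paths[["catalog"]])
  write.csv(corpus$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
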