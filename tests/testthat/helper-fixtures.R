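# Small hand-written catalog: 3 adult + 2 paediatric conditions, all
# three representations identical (keeps per-metric oracles simple).
make_test_catalog <- function() {
  mk <- function(id, ag, name, u1, u2, u3, fixed = NULL) {
    units <- list(`1` = u1, `2` = u2, `3` = u3)
    cpc_definition(id, ag, name,
                   representations = list(criteria_words = units,
                                          medical_terms = units,
                                          keywords = units),
                   fixed_category = fixed)
  }
  cpc_catalog(list(
    mk("ad-hearing-loss", "adult", "hearing loss",
       c("hear", "loss", "sudden"), c("hear", "loss", "gradual"),
       c("hear", "aid")),
    mk("ad-tinnitus", "adult", "tinnitus",
       c("ring", "ear", "puls"), c("ring", "noise"),
       c("ear", "noise", "chronic")),
    mk("ad-neck-mass", "adult", "head and neck mass",
       c("neck", "mass"), character(0), character(0), fixed = 1L),
    mk("pa-otitis", "paediatric", "otitis media",
       c("ear", "pain", "fever"), c("ear", "fluid"), c("ear", "glue")),
    mk("pa-tonsillitis", "paediatric", "tonsillitis (recurrent)",
       c("throat", "sore", "tonsil"), c("tonsil", "swell"),
       c("snore", "tonsil"))
  ))
}

# naive recursive edit-distance oracle (independent of the DP kernel)
lev_ref <- function(a, b) {
  na <- nchar(a)
  nb <- nchar(b)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  min(lev_ref(substr(a, 2, na), b) + 1L,
      lev_ref(a, substr(b, 2, nb)) + 1L,
      lev_ref(substr(a, 2, na), substr(b, 2, nb)) + cost)
}

random_tokens <- function(n, vocab = letters[1:6]) {
  sample(vocab, n, replace = TRUE)
}

random_string <- function(max_len = 8L, alphabet = c("a", "b", "c")) {
  n <- sample(0:max_len, 1L)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small prepared referral data.frame built directly from token lists
make_prepared <- function(terms, age_group = "adult", cpc_label = NA,
                          category = NA_integer_) {
  n <- length(terms)
  data.frame(
    referral_id = sprintf("T%03d", seq_len(n)),
    text = vapply(terms, paste, "", collapse = " "),
    dob = as.Date("1980-01-01"),
    submitted = as.Date("2020-01-01"),
    cpc_label = rep_len(cpc_label, n),
    category = rep_len(category, n),
    lodgment = NA_character_,
    stringsAsFactors = FALSE
  ) -> df
  df$medical_terms <- terms
  df$degraded <- FALSE
  df$age_group <- rep_len(age_group, n)
  df
}

cpc_agreement <- function(results, truth) {
  m <- match(results$referral_id, truth$referral_id)
  mean(results$cpc_id == truth$true_cpc[m])
}

category_agreement <- function(results, truth) {
  m <- match(results$referral_id, truth$referral_id)
  mean(results$category == truth$true_category[m])
}
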