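# Seeded synthetic MEDLINE-style corpus generator with gold-standard labels.
#
# The generator emulates the statistical structure of a hand-searched
# gold-standard pool: a small prevalence of cluster randomized trials among
# a large body of journal articles, per-year probabilities that a CRT's
# design is clearly phrased in the title or abstract (rising over time),
# imperfect publication-type indexing of trials, and broad
# intervention/health-promotion vocabulary planted in both trials and
# non-trial articles at different rates (precision of the shipped filters
# depends on those rates). Text is template-based: determinism and
# label/text consistency outweigh realism.

synth_topics <- c(
  "smoking cessation counselling", "hand hygiene compliance",
  "vitamin d supplementation", "influenza vaccination uptake",
  "diabetes self management education", "asthma action plans",
  "depression screening", "antibiotic prescribing feedback",
  "dietary counselling", "fall prevention exercises",
  "breastfeeding support", "malaria prophylaxis adherence"
)
synth_drugs <- c("metformin", "atorvastatin", "sertraline", "salbutamol",
                 "amoxicillin", "enalapril")
synth_diseases <- c("chronic kidney disease", "atrial fibrillation",
                    "osteoarthritis", "hepatitis b", "migraine")
synth_journals <- c("Journal of Synthetic Trials", "Annals of Simulated Medicine",
                    "Synthetic Public Health", "Archives of Generated Epidemiology",
                    "Simulated Primary Care", "Trials in Silico")
# unit nouns used in generated unit-of-randomization phrasing; kept clear of
# cluster/group/communit stems so they can never form a CLEAR design phrase
synth_unit_plural <- c("schools", "practices", "hospitals", "villages",
                       "wards", "teams", "churches")
synth_unit_singular <- c("physician", "practice", "hospital", "village")

broad_mesh_bank <- c("Cluster Analysis", "Health Promotion",
                     "Program Evaluation", "Health Education")
unrelated_mesh_bank <- c("Biomarkers", "Neoplasms", "Risk Factors",
                         "Prevalence", "Epidemiologic Methods")

clear_design_phrases <- c("cluster randomised", "cluster randomized",
                          "cluster-randomized", "group randomised",
                          "group randomized", "community randomised",
                          "community randomized")

#' Phrase templates used by the synthetic corpus generator
#'
#' Exposes the template strings per identifiability class, including the
#' distractor forms planted in individually randomized trials ("patients in
#' the participating hospitals were randomly assigned") that unit-based
#' electronic searches must not mistake for cluster designs.
#'
#' @return A named list of character vectors: `clear`, `unit`, `none`,
#'   `distractor`.
#' @export
phrase_bank <- function() {
  list(
    clear = clear_design_phrases,
    unit = c("%UNITS% were randomised to the programme or to control",
             "%UNITS% were randomized to the programme or to control",
             "patients were randomized by %UNIT%",
             "randomization by %UNIT% was used to limit contamination"),
    none = c("participants were randomly assigned to the programme or usual care",
             "high schools (N = %N%) paired on enrolment size, racial composition and class structure were randomized"),
    distractor = c("patients in the participating hospitals were randomly assigned to %DRUG% or placebo")
  )
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults reproduce the structure of the published gold-standard pool:
#' CRT prevalence 162/25707; yearly article weights proportional to the
#' gold-standard trials per year 2000-2007; per-year probability that a CRT
#' is clearly identified following the published yearly proportions (rising
#' from ~0.29 in 2000 to ~0.65 in 2007); the non-clear mass split
#' UNIT:NONE = 46:38; publication-type indexing sensitivity 0.938 for
#' trials. Non-trial composition (individually randomized trials 0.064,
#' health-promotion/observational 0.11, unrelated 0.826) and broad-term
#' carriage rates (0.92 in CRTs, 0.42 in individually randomized trials)
#' are back-derived from the published fall-out figures of the
#' publication-type, broad-term and highest-precision filters (6.0%, 13.7%,
#' 2.5%).
#'
#' @param n_articles Number of citations to generate.
#' @param crt_prevalence Proportion of articles that are CRTs.
#' @param years Integer vector of publication years.
#' @param year_weights Sampling weights per year (normalized internally).
#' @param clear_prob_by_year Per-year probability a CRT is `CLEAR`; either a
#'   vector named by year or a single number.
#' @param unit_none_ratio Two-element ratio splitting non-clear CRTs between
#'   `UNIT` and `NONE`.
#' @param pt_tag_sensitivity Probability a trial (cluster or individually
#'   randomized) carries the publication type "Randomized Controlled Trial".
#' @param non_trial_mix Named proportions (`ind_trial`,
#'   `health_promotion`, `unrelated`) for non-CRT articles; must sum to 1.
#' @param crt_broad_term_prob Probability a CRT carries broad
#'   intervention/health-promotion vocabulary (textword or MeSH).
#' @param ind_broad_term_prob The same probability for individually
#'   randomized trials.
#' @param ind_distractor_prob Probability an individually randomized trial
#'   uses the "participating hospitals" distractor phrasing.
#' @param community_phrase_prob Probability a health-promotion article
#'   mentions a "community intervention" programme.
#' @param over_weight_2006 If `TRUE`, triple the weight of year 2006,
#'   mimicking a design in which one year is covered by a larger journal
#'   subset.
#' @param seed Integer seed; the same seed and configuration give a
#'   byte-identical corpus and label set.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_articles = 2000,
                             crt_prevalence = 162 / 25707,
                             years = 2000:2007,
                             year_weights = c(14, 16, 9, 19, 15, 20, 52, 17),
                             clear_prob_by_year = NULL,
                             unit_none_ratio = c(46, 38),
                             pt_tag_sensitivity = 0.938,
                             non_trial_mix = c(ind_trial = 0.064,
                                               health_promotion = 0.11,
                                               unrelated = 0.826),
                             crt_broad_term_prob = 0.92,
                             ind_broad_term_prob = 0.42,
                             ind_distractor_prob = 0.15,
                             community_phrase_prob = 0.04,
                             over_weight_2006 = FALSE,
                             seed = 1L) {
  if (is.null(clear_prob_by_year)) {
    defaults <- c(`2000` = 4 / 14, `2001` = 1 / 16, `2002` = 1 / 9,
                  `2003` = 10 / 19, `2004` = 8 / 15, `2005` = 13 / 20,
                  `2006` = 30 / 52, `2007` = 11 / 17)
    clear_prob_by_year <- if (all(as.character(years) %in% names(defaults)))
      defaults[as.character(years)]
    else stats::setNames(rep(78 / 162, length(years)), years)
  }
  if (length(clear_prob_by_year) == 1L && is.null(names(clear_prob_by_year)))
    clear_prob_by_year <- stats::setNames(rep(clear_prob_by_year, length(years)),
                                          years)
  cfg <- structure(list(
    n_articles = as.integer(n_articles),
    crt_prevalence = crt_prevalence,
    years = as.integer(years),
    year_weights = as.numeric(year_weights),
    clear_prob_by_year = clear_prob_by_year,
    unit_none_ratio = as.numeric(unit_none_ratio),
    pt_tag_sensitivity = pt_tag_sensitivity,
    non_trial_mix = non_trial_mix,
    crt_broad_term_prob = crt_broad_term_prob,
    ind_broad_term_prob = ind_broad_term_prob,
    ind_distractor_prob = ind_distractor_prob,
    community_phrase_prob = community_phrase_prob,
    over_weight_2006 = isTRUE(over_weight_2006),
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$crt_prevalence, cfg$pt_tag_sensitivity,
             cfg$crt_broad_term_prob, cfg$ind_broad_term_prob,
             cfg$ind_distractor_prob, cfg$community_phrase_prob,
             cfg$clear_prob_by_year)
  if (any(probs < 0 | probs > 1))
    stop_hedge("all probabilities must lie in [0, 1]")
  if (cfg$n_articles < 0) stop_hedge("n_articles must be non-negative")
  if (length(cfg$year_weights) != length(cfg$years))
    stop_hedge("year_weights must match years in length")
  if (any(cfg$year_weights < 0) || sum(cfg$year_weights) <= 0)
    stop_hedge("year_weights must be non-negative with a positive sum")
  if (!setequal(names(cfg$non_trial_mix),
                c("ind_trial", "health_promotion", "unrelated")))
    stop_hedge("non_trial_mix needs names ind_trial, health_promotion, unrelated")
  if (abs(sum(cfg$non_trial_mix) - 1) > 1e-8)
    stop_hedge("non_trial_mix proportions must sum to 1")
  if (length(cfg$unit_none_ratio) != 2 || any(cfg$unit_none_ratio < 0) ||
      sum(cfg$unit_none_ratio) <= 0)
    stop_hedge("unit_none_ratio must be two non-negative numbers")
  if (!all(as.character(cfg$years) %in% names(cfg$clear_prob_by_year)))
    stop_hedge("clear_prob_by_year must cover every year")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> n=", x$n_articles,
      " prevalence=", signif(x$crt_prevalence, 3),
      " years=", min(x$years), "-", max(x$years),
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

pick <- function(x) x[[sample.int(length(x), 1L)]]

sentence_case <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Generate title and abstract text for one synthetic citation
#'
#' Draws from the template [phrase_bank()] so that the text is consistent
#' with the requested identifiability class under
#' [classify_identifiability()]: a `CLEAR` trial contains a
#' cluster/group/community design phrase, a `UNIT` trial contains
#' unit-of-randomization phrasing but no design phrase, a `NONE` trial
#' contains neither. Uses the current RNG state.
#'
#' @param role One of `crt`, `ind_trial`, `health_promotion`, `unrelated`.
#' @param identifiability For `crt`: `CLEAR`, `UNIT` or `NONE`.
#' @param broad_textword Include broad "interventions" vocabulary.
#' @param community_phrase For `health_promotion`: mention a community
#'   intervention programme.
#' @param unit_distractor For `ind_trial`: use the "participating
#'   hospitals" distractor phrasing.
#' @return List with `title` and `abstract`.
#' @export
sample_citation_text <- function(role,
                                 identifiability = NA_character_,
                                 broad_textword = FALSE,
                                 community_phrase = FALSE,
                                 unit_distractor = FALSE) {
  bank <- phrase_bank()
  topic <- pick(synth_topics)
  broad_tail <- if (broad_textword)
    " The interventions were delivered over six months." else ""
  if (role == "crt") {
    if (identical(identifiability, "CLEAR")) {
      dp <- pick(bank$clear)
      title <- sentence_case(paste0("a ", dp, " trial of ", topic))
      abstract <- paste0(
        sentence_case(paste0("we conducted a ", dp,
                             " trial evaluating ", topic, ".")),
        " Participants were enrolled at baseline and followed for twelve months.",
        broad_tail)
    } else if (identical(identifiability, "UNIT")) {
      tpl <- pick(bank$unit)
      tpl <- gsub("%UNITS%", pick(synth_unit_plural), tpl)
      tpl <- gsub("%UNIT%", pick(synth_unit_singular), tpl)
      title <- sentence_case(paste0("effect of ", topic,
                                    " on patient outcomes: a controlled trial"))
      abstract <- paste0(sentence_case(paste0(tpl, ".")),
                         " Outcomes were assessed after one year.", broad_tail)
    } else {
      tpl <- pick(bank$none)
      tpl <- gsub("%N%", as.character(sample(10:40, 1L)), tpl)
      title <- sentence_case(paste0("a randomised controlled trial of ", topic))
      abstract <- paste0(sentence_case(paste0(tpl, ".")),
                         " Follow up lasted two years.", broad_tail)
    }
  } else if (role == "ind_trial") {
    drug <- pick(synth_drugs)
    title <- sentence_case(paste0("a randomized controlled trial of ", drug,
                                  " for ", pick(synth_diseases)))
    core <- if (unit_distractor)
      gsub("%DRUG%", drug, bank$distractor[[1]])
    else paste0("patients were randomly assigned to ", drug, " or placebo")
    abstract <- paste0(sentence_case(paste0(core, ".")),
                       " The primary outcome was assessed at one year.",
                       broad_tail)
  } else if (role == "health_promotion") {
    title <- sentence_case(paste0(topic, " promotion programme: an evaluation"))
    core <- if (community_phrase)
      "a community intervention programme was evaluated across several districts"
    else paste0("an outreach programme addressing ", topic,
                " was evaluated before and after implementation")
    abstract <- paste0(sentence_case(paste0(core, ".")),
                       " Uptake was measured with routine data.", broad_tail)
  } else {
    dis <- pick(synth_diseases)
    title <- sentence_case(paste0("serum biomarkers of ", dis,
                                  ": a cross sectional study"))
    abstract <- paste0("We measured candidate biomarkers in adults with ",
                       dis, ". Associations were estimated with regression models.")
  }
  list(title = title, abstract = abstract)
}

decorate_mesh <- function(heading) {
  r <- stats::runif(1)
  if (r < 0.2) paste0("*", heading)
  else if (r < 0.4) paste0(heading, "/methods")
  else heading
}

#' Generate a labelled synthetic corpus
#'
#' Deterministic under the configuration's seed: the same
#' [generator_config()] always yields a byte-identical corpus and label set.
#' Every generated citation's text is consistent with its identifiability
#' label under [classify_identifiability()]; this is verified before
#' returning.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_corpus` with elements `corpus`
#'   ([medline_corpus()]), `labels` ([gold_labels()]) and `config`.
#' @examples
#' sim <- generate_corpus(generator_config(n_articles = 200, seed = 7))
#' sim$corpus
#' @export
generate_corpus <- function(config) {
  validate_generator_config(config)
  if (config$n_articles == 0L) {
    return(structure(list(corpus = medline_corpus(provenance = "synthetic"),
                          labels = gold_labels(character(0), logical(0),
                                               character(0), integer(0)),
                          config = config),
                     class = "synthetic_corpus"))
  }
  with_seed(config$seed, {
    n <- config$n_articles
    years <- sample(config$years, n, replace = TRUE, prob = config$year_weights *
                      ifelse(config$over_weight_2006 & config$years == 2006, 3, 1))
    is_crt <- stats::runif(n) < config$crt_prevalence
    roles <- character(n)
    roles[is_crt] <- "crt"
    n_non <- sum(!is_crt)
    roles[!is_crt] <- sample(names(config$non_trial_mix), n_non, replace = TRUE,
                             prob = config$non_trial_mix)
    ident <- rep(NA_character_, n)
    p_unit <- config$unit_none_ratio[1] / sum(config$unit_none_ratio)
    for (i in which(is_crt)) {
      if (stats::runif(1) < config$clear_prob_by_year[[as.character(years[i])]])
        ident[i] <- "CLEAR"
      else ident[i] <- if (stats::runif(1) < p_unit) "UNIT" else "NONE"
    }
    cits <- vector("list", n)
    for (i in seq_len(n)) {
      role <- roles[i]
      is_trial <- role %in% c("crt", "ind_trial")
      broad <- switch(role,
        crt = stats::runif(1) < config$crt_broad_term_prob,
        ind_trial = stats::runif(1) < config$ind_broad_term_prob,
        health_promotion = TRUE,
        unrelated = FALSE)
      # carriers split their broad signal between MeSH and textword
      broad_mesh <- broad && stats::runif(1) < 0.55
      broad_tw <- broad && stats::runif(1) < 0.7
      if (broad && !broad_mesh && !broad_tw) broad_tw <- TRUE
      if (role == "health_promotion") broad_mesh <- TRUE
      txt <- sample_citation_text(
        role, identifiability = ident[i], broad_textword = broad_tw,
        community_phrase = role == "health_promotion" &&
          stats::runif(1) < config$community_phrase_prob,
        unit_distractor = role == "ind_trial" &&
          stats::runif(1) < config$ind_distractor_prob)
      mesh <- character(0)
      if (role == "unrelated") {
        r <- stats::runif(1)
        mesh <- if (r < 0.10) "Animals"
                else if (r < 0.15) c("Animals", "Humans") else "Humans"
        mesh <- c(mesh, sample(unrelated_mesh_bank, 2L))
      } else {
        mesh <- "Humans"
      }
      if (broad_mesh) {
        k <- 1L + (stats::runif(1) < 0.3)
        mesh <- c(mesh, vapply(sample(broad_mesh_bank, k), decorate_mesh,
                               character(1)))
      }
      pt <- "Journal Article"
      if (is_trial && stats::runif(1) < config$pt_tag_sensitivity)
        pt <- c("Randomized Controlled Trial", pt)
      cits[[i]] <- citation_record(
        uid = sprintf("%08d", 10000000L + i),
        title = txt$title, abstract = txt$abstract,
        mesh_terms = mesh, pub_types = pt,
        journal = pick(synth_journals), year = years[i])
    }
    corpus <- medline_corpus(cits, provenance = sprintf(
      "synthetic corpus (n=%d, seed=%d)", n, config$seed))
    labels <- gold_labels(corpus_uids(corpus), is_crt, ident, years)
    # post-condition: generated text agrees with the planted label
    for (i in which(is_crt)) {
      got <- classify_identifiability(cits[[i]])
      if (!identical(got, ident[i]))
        stop_hedge("internal generator inconsistency at ", cits[[i]]$uid,
                   ": labelled ", ident[i], " but classified ", got)
    }
    structure(list(corpus = corpus, labels = labels, config = config),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", corpus_size(x$corpus), " citations, ",
      sum(x$labels$is_crt), " CRTs (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}
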