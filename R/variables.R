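#' Time-since-event category
#'
#' Bins the state of an event clock at the start of a focal into the six
#' ordered states used by the reactionary models: no event yet that day,
#' event ongoing, or elapsed time since the event ended in half-open bins
#' [0,5), [5,10), [10,15), [15,Inf) minutes. An ongoing event dominates any
#' earlier completed event of the same type.
#'
#' @param elapsed_min minutes from the last event's end to the focal start
#'   (`NA` when no event has occurred that day). Negative values with
#'   `ongoing = FALSE` are inconsistent and raise an error.
#' @param ongoing logical, whether an event is in progress at focal start.
#' @return factor with levels [time_since_levels()].
#' @export
time_since_category <- function(elapsed_min, ongoing = FALSE) {
  n <- max(length(elapsed_min), length(ongoing))
  elapsed_min <- rep_len(elapsed_min, n)
  ongoing <- rep_len(ongoing, n)
  if (any(!ongoing & !is.na(elapsed_min) & elapsed_min < 0))
    stop("time_since_category: event ends after focal start but not flagged ongoing")
  out <- character(n)
  out[ongoing] <- "ongoing"
  idx <- !ongoing
  e <- elapsed_min[idx]
  out[idx] <- ifelse(is.na(e), "no_event",
              ifelse(e < 5, "post_0_5",
              ifelse(e < 10, "post_5_10",
              ifelse(e < 15, "post_10_15", "post_gt15"))))
  factor(out, levels = time_since_levels())
}

check_behaviour_names <- function(nm) {
  vocab <- c(unlist(behaviour_vocabulary(), use.names = FALSE))
  bad <- setdiff(nm, vocab)
  if (length(bad))
    stop(sprintf("unknown behaviour name(s): %s", paste(bad, collapse = ", ")))
  invisible(vocab)
}

#' Time spent in engaged / not-engaged behaviours
#'
#' Engaged behaviours require visual attention and use of the hands
#' (grooming another, self-grooming, digging, searching substrate, picking,
#' aggression/play); everything else in the vocabulary (resting, chewing,
#' mating, self-scratch, receiving grooming, drinking, movement,
#' communication, biting, handling, posture) leaves the eyes free. The two
#' totals partition the recorded behaviour budget.
#'
#' @param behaviour_seconds named numeric vector or list mapping behaviour
#'   names to seconds.
#' @return total seconds.
#' @export
engaged_time <- function(behaviour_seconds) {
  b <- unlist(behaviour_seconds)
  if (!length(b)) return(0)
  check_behaviour_names(names(b))
  sum(b[names(b) %in% behaviour_vocabulary()$engaged])
}

#' @rdname engaged_time
#' @export
not_engaged_time <- function(behaviour_seconds) {
  b <- unlist(behaviour_seconds)
  if (!length(b)) return(0)
  check_behaviour_names(names(b))
  sum(b[names(b) %in% behaviour_vocabulary()$not_engaged])
}

#' Average a context variable over start and end assessments
#'
#' Contextual covariates (neighbour count, visibility, observer distance)
#' are assessed at the start and end of each focal and averaged to a single
#' value. A missing end assessment propagates `NA` with a warning.
#'
#' @param start_value,end_value numeric vectors.
#' @return elementwise arithmetic mean.
#' @export
average_context <- function(start_value, end_value) {
  if (any(is.na(end_value)))
    warning("average_context: missing end assessment; returning NA")
  (start_value + end_value) / 2
}

#' Count within-group social threats
#'
#' A social threat is a higher-ranked neighbour within 5 m that is not a
#' member of the focal animal's grooming clique: the number of higher-ranked
#' neighbours minus the number of higher-ranked clique members (floored at
#' zero).
#'
#' @param neighbour_ids character vector of neighbour identities.
#' @param ranking named integer vector of rank positions (1 = top) for all
#'   individuals.
#' @param cliques named vector of clique labels for all individuals.
#' @param focal_id the focal animal's id.
#' @return list with `n_neighbours`, `n_higher_ranked`, `n_social_threats`.
#' @export
count_social_threats <- function(neighbour_ids, ranking, cliques, focal_id) {
  neighbour_ids <- neighbour_ids[nzchar(neighbour_ids)]
  if (focal_id %in% neighbour_ids)
    stop("count_social_threats: focal appears in its own neighbour set")
  absent <- setdiff(c(neighbour_ids, focal_id), names(ranking))
  if (length(absent))
    stop(sprintf("count_social_threats: ids missing from ranking: %s",
                 paste(absent, collapse = ", ")))
  absent <- setdiff(c(neighbour_ids, focal_id), names(cliques))
  if (length(absent))
    stop(sprintf("count_social_threats: ids missing from cliques: %s",
                 paste(absent, collapse = ", ")))
  higher <- neighbour_ids[ranking[neighbour_ids] < ranking[[focal_id]]]
  same_clique <- higher[cliques[higher] == cliques[[focal_id]]]
  list(n_neighbours = length(neighbour_ids),
       n_higher_ranked = length(higher),
       n_social_threats = max(0L, length(higher) - length(same_clique)))
}

#' Build the analysis table
#'
#' Joins everything the models consume into one row per focal observation:
#' the raw focal fields; engaged / not-engaged time budgets; per-event-type
#' time-since categories; I&SI dominance rank and the within-group social
#' threat count (via grooming cliques); and the spatial covariates looked up
#' at the focal's grid cell (leopard risk, inverted utilisation
#' distribution, familiarity class, inter-group encounter risk). Factors are
#' coded with fixed reference levels (age-sex: adult-male; habitat: forest;
#' time-since: no_event; position: central; familiarity: core; food: none).
#'
#' @param focals a [simulate_focals()] table (with responses filled by
#'   [generate_looking()], or ingested data of the same schema).
#' @param roster the group roster.
#' @param agonistic directed interaction count matrix.
#' @param grooming symmetric grooming weight matrix.
#' @param layers list of spatial layers as from [simulate_landscape()].
#' @param ranking optional precomputed [isi_rank()] result.
#' @param clique_labels optional precomputed [detect_cliques()] result.
#' @return data.frame of class `look_table`.
#' @export
derive_analysis_table <- function(focals, roster, agonistic, grooming, layers,
                                  ranking = NULL, clique_labels = NULL) {
  if (is.null(ranking)) ranking <- isi_rank(agonistic)
  if (is.null(clique_labels)) clique_labels <- detect_cliques(grooming)
  rank_pos <- stats::setNames(match(rownames(agonistic), ranking$order),
                              rownames(agonistic))
  tab <- as.data.frame(focals)

  tab$age_sex_class <- factor(
    roster$age_sex_class[match(tab$individual_id, roster$individual_id)],
    levels = age_sex_levels())
  tab$tolerance <- roster$tolerance_score[match(tab$individual_id,
                                                roster$individual_id)]
  tab$rank <- as.numeric(rank_pos[tab$individual_id])

  vocab <- behaviour_vocabulary()
  beh_cols <- function(set) paste0("behav_", set)
  tab$engaged_s <- rowSums(tab[, beh_cols(vocab$engaged), drop = FALSE])
  tab$not_engaged_s <- rowSums(tab[, beh_cols(vocab$not_engaged), drop = FALSE])

  for (ev in event_types()) {
    tab[[paste0("ts_", ev)]] <- time_since_category(
      tab[[paste0("ev_", ev, "_elapsed")]],
      tab[[paste0("ev_", ev, "_ongoing")]])
  }

  threats <- t(vapply(seq_len(nrow(tab)), function(r) {
    nb <- strsplit(tab$neighbour_ids[r], ";", fixed = TRUE)[[1]]
    st <- count_social_threats(nb, rank_pos, clique_labels,
                               tab$individual_id[r])
    c(st$n_higher_ranked, st$n_social_threats)
  }, numeric(2)))
  tab$n_higher_ranked <- threats[, 1]
  tab$n_social_threats <- threats[, 2]

  ud_s <- linear_stretch(layers$ud)
  enc_s <- linear_stretch(layers$encounter_intensity)
  risk <- encounter_risk_layer(enc_s, ud_s)
  ud_at <- layer_lookup(ud_s, tab$grid_row, tab$grid_col)
  tab$inverted_ud <- 1 - ud_at
  tab$familiarity <- familiarity_class(ud_at, ud_s)
  tab$leopard_rsf <- layer_lookup(layers$leopard_rsf, tab$grid_row, tab$grid_col)
  er <- layer_lookup(risk, tab$grid_row, tab$grid_col)
  er[is.na(er)] <- 0   # cells outside the used range carry no encounter risk
  tab$encounter_risk <- er

  tab$habitat <- factor(tab$habitat, levels = habitat_levels())
  tab$spatial_position <- factor(tab$spatial_position,
                                 levels = c("central", "peripheral"))
  tab$food_item <- factor(tab$food_item, levels = food_item_levels())
  tab$observer_moved <- as.logical(tab$observer_moved)
  tab$visibility <- tab$visibility_pct

  class(tab) <- c("look_table", "data.frame")
  tab
}
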