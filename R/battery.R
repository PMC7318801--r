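#' Construct a dilemma battery for one experimental condition
#'
#' A battery for one condition consists of `n_pairs` incongruent dilemmas
#' (the harmful action maximizes overall benefit, so harm-rejection and
#' outcome-maximization inclinations conflict) each matched with a congruent
#' twin (the benefit of acting is minimized, so both inclinations favor
#' rejection). All items in a battery share the condition's instrumentality
#' (whether harm is a means to the good outcome or a side-effect of it) and
#' personal-force level (whether the agent causes harm directly or merely
#' initiates a process).
#'
#' @param instrumentality `"means"` or `"side_effect"`.
#' @param personal_force `"personal"` or `"impersonal"`.
#' @param n_pairs number of congruent/incongruent pairs (default 10, giving
#'   the standard 20-item battery).
#' @param id_prefix optional prefix for item and pair ids; defaults to a
#'   short tag built from the condition.
#' @return data.frame with columns `item_id`, `pair_id`, `congruency`,
#'   `instrumentality`, `personal_force`, `counterbalance_tags`.
#' @export
#' @examples
#' b <- dilemma_battery("means", "personal")
#' nrow(b)  # 20
dilemma_battery <- function(instrumentality = c("means", "side_effect"),
                            personal_force = c("personal", "impersonal"),
                            n_pairs = 10, id_prefix = NULL) {
  instrumentality <- match.arg(instrumentality)
  personal_force <- match.arg(personal_force)
  stopifnot(n_pairs >= 1)
  if (is.null(id_prefix)) {
    id_prefix <- paste0(substr(instrumentality, 1, 1),
                        substr(personal_force, 1, 1))
  }
  pair_id <- sprintf("%s_p%02d", id_prefix, seq_len(n_pairs))
  # counterbalanced nuisance features (benefit recipient, evitability)
  tags <- rep(c("benefit-other;evitable", "benefit-self;inevitable"),
              length.out = n_pairs)
  data.frame(
    item_id = c(paste0(pair_id, "_inc"), paste0(pair_id, "_con")),
    pair_id = rep(pair_id, 2),
    congruency = rep(c("incongruent", "congruent"), each = n_pairs),
    instrumentality = instrumentality,
    personal_force = personal_force,
    counterbalance_tags = rep(tags, 2),
    stringsAsFactors = FALSE
  )
}

#' Construct the batteries of a full factorial design
#'
#' @param instrumentality,personal_force character vectors of factor levels
#'   to cross; the default gives the four-condition (2 x 2) design.
#' @param n_pairs pairs per condition battery.
#' @return data.frame stacking one [dilemma_battery()] per condition.
#' @export
full_battery <- function(instrumentality = c("means", "side_effect"),
                         personal_force = c("personal", "impersonal"),
                         n_pairs = 10) {
  grid <- expand.grid(instrumentality = instrumentality,
                      personal_force = personal_force,
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    dilemma_battery(grid$instrumentality[i], grid$personal_force[i],
                    n_pairs = n_pairs)
  }))
}

#' Validate a dilemma battery
#'
#' Violations are returned as data, not raised as errors: unpaired items,
#' pairs whose two members disagree on instrumentality or personal force or
#' congruency, duplicated item ids, and condition cells that do not hold
#' exactly `n_pairs` pairs.
#'
#' @param items battery data.frame as from [dilemma_battery()].
#' @param n_pairs expected number of pairs per condition (default 10).
#' @return data.frame with columns `rule`, `id`, `message`; zero rows iff
#'   the battery is well-formed.
#' @export
validate_battery <- function(items, n_pairs = 10) {
  stopifnot(nrow(items) > 0)
  v <- list()
  add <- function(rule, id, message) {
    v[[length(v) + 1]] <<- data.frame(rule = rule, id = id,
                                      message = message,
                                      stringsAsFactors = FALSE)
  }
  dup <- unique(items$item_id[duplicated(items$item_id)])
  for (d in dup) add("duplicate_item", d, "item_id appears more than once")

  for (p in unique(items$pair_id)) {
    sub <- items[items$pair_id == p, , drop = FALSE]
    if (nrow(sub) != 2 ||
        !setequal(sub$congruency, c("congruent", "incongruent"))) {
      add("unpaired_item", p,
          "pair must hold exactly one congruent and one incongruent item")
      next
    }
    if (length(unique(sub$instrumentality)) != 1 ||
        length(unique(sub$personal_force)) != 1) {
      add("factor_mismatch", p,
          "pair members differ in instrumentality or personal force")
    }
  }

  cond <- interaction(items$instrumentality, items$personal_force, drop = TRUE)
  for (cl in levels(cond)) {
    np <- length(unique(items$pair_id[cond == cl]))
    if (np != n_pairs) {
      add("wrong_pair_count", cl,
          sprintf("condition has %d pairs, expected %d", np, n_pairs))
    }
  }
  if (length(v) == 0) {
    return(data.frame(rule = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Generate a semi-random presentation order
#'
#' Uniform permutations of the battery are rejection-sampled until one
#' satisfies both ordering constraints: (a) no more than `max_run`
#' consecutive items share a congruency status, and (b) at least
#' `min_between` other dilemmas separate the two members of every
#' congruent/incongruent pair. The accepted order is therefore uniform over
#' the set of valid orders.
#'
#' @param items well-formed single-condition battery (20 items by default).
#' @param seed integer seed; the same seed always yields the same order.
#' @param max_run maximum allowed same-congruency run length (default 3).
#' @param min_between minimum number of other items strictly between pair
#'   members (default 6, i.e. positional gap of at least 7).
#' @param max_attempts rejection-sampling budget before giving up.
#' @return object of class `pd_order`: list with `item_id` (the ordered
#'   ids), `seed`, and `condition`.
#' @export
generate_order <- function(items, seed, max_run = 3, min_between = 6,
                           max_attempts = 1000000L) {
  bv <- validate_battery(items, n_pairs = length(unique(items$pair_id)))
  if (nrow(bv) > 0) {
    stop("battery is not well-formed; see validate_battery()")
  }
  if (length(unique(items$instrumentality)) != 1 ||
      length(unique(items$personal_force)) != 1) {
    stop("generate_order() expects a single-condition battery")
  }
  set.seed(as.integer(seed))
  cong <- as.integer(items$congruency == "congruent")
  pair <- as.integer(factor(items$pair_id)) - 1L
  idx <- .order_rejection_sample(cong, pair, as.integer(max_run),
                                 as.integer(min_between),
                                 as.integer(max_attempts))
  if (length(idx) == 0) {
    stop("no valid order found within max_attempts; ",
         "the battery constraints may be unsatisfiable")
  }
  structure(list(item_id = items$item_id[idx],
                 seed = as.integer(seed),
                 condition = c(instrumentality = items$instrumentality[1],
                               personal_force = items$personal_force[1])),
            class = "pd_order")
}

#' @export
print.pd_order <- function(x, ...) {
  cat("Presentation order (seed ", x$seed, ", ",
      paste(x$condition, collapse = "/"), "):\n", sep = "")
  cat(" ", paste(x$item_id, collapse = " "), "\n")
  invisible(x)
}

#' Validate a presentation order
#'
#' Scans the sequence for (a) runs of more than `max_run` items with the
#' same congruency and (b) pairs whose members have fewer than `min_between`
#' other items strictly between them.
#'
#' @param order a `pd_order` or a character vector of item ids.
#' @param items the battery the order permutes.
#' @inheritParams generate_order
#' @return data.frame of violations (`rule`, `id`, `message`); zero rows
#'   iff the order is valid.
#' @export
validate_order <- function(order, items, max_run = 3, min_between = 6) {
  ids <- if (inherits(order, "pd_order")) order$item_id else order
  if (!setequal(ids, items$item_id) || length(ids) != nrow(items)) {
    stop("order is not a permutation of the battery's item ids")
  }
  v <- list()
  add <- function(rule, id, message) {
    v[[length(v) + 1]] <<- data.frame(rule = rule, id = id,
                                      message = message,
                                      stringsAsFactors = FALSE)
  }
  cong <- items$congruency[match(ids, items$item_id)]
  r <- rle(cong)
  bad <- which(r$lengths > max_run)
  for (k in bad) {
    add("congruency_run", r$values[k],
        sprintf("run of %d consecutive %s items", r$lengths[k], r$values[k]))
  }
  pair <- items$pair_id[match(ids, items$item_id)]
  for (p in unique(pair)) {
    pos <- which(pair == p)
    if (length(pos) == 2 && (abs(diff(pos)) - 1) < min_between) {
      add("pair_too_close", p,
          sprintf("only %d items between pair members", abs(diff(pos)) - 1L))
    }
  }
  if (length(v) == 0) {
    return(data.frame(rule = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Freeze a fixed set of presentation orders
#'
#' Classic designs use a handful of pre-generated semi-random orders per
#' condition; this derives `n_orders` orders deterministically from one
#' root seed.
#'
#' @inheritParams generate_order
#' @param n_orders number of orders to freeze (default 5).
#' @return list of `pd_order` objects.
#' @export
freeze_orders <- function(items, seed, n_orders = 5, max_run = 3,
                          min_between = 6, max_attempts = 1000000L) {
  lapply(seq_len(n_orders), function(k) {
    generate_order(items, seed = as.integer(seed) + k - 1L,
                   max_run = max_run, min_between = min_between,
                   max_attempts = max_attempts)
  })
}

#' Read or write a battery file
#'
#' CSV or JSON is chosen by file extension.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return `read_battery()`: battery data.frame.
#' @export
read_battery <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

#' @rdname read_battery
#' @param items battery data.frame.
#' @export
write_battery <- function(items, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(items, path, dataframe = "rows", pretty = TRUE)
  } else {
    write.csv(items, path, row.names = FALSE)
  }
  invisible(path)
}

#' Export presentation orders as JSON
#'
#' @param orders list of `pd_order` objects.
#' @param path output path.
#' @export
write_orders <- function(orders, path) {
  payload <- lapply(orders, function(o) {
    list(seed = o$seed, condition = as.list(o$condition),
         item_id = o$item_id)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
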