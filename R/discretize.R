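#' Discretization rules
#'
#' A discretization spec maps each retained attribute to one rule converting
#' its raw values into category labels. Four rule kinds cover the study
#' designs:
#'
#' * `rule_categorical()` -- passthrough of a categorical value, with optional
#'   label recoding and an optional regex `strip` applied first (used e.g. to
#'   strip record-id suffixes from a class column).
#' * `rule_boolean()` -- normalizes the boolean spellings found in clinical
#'   exports (`f/t`, `0/1`, `N/Y`, `no/yes`, `false/true`) to the uniform
#'   levels `False`/`True`.
#' * `rule_normal_range(lo, hi)` -- laboratory reference range; values inside
#'   the closed interval `[lo, hi]` map to `Normal`, everything else to
#'   `Abnormal`.
#' * `rule_bins(breaks)` -- ordered half-open bins `[lo, hi)` with the last
#'   bin closed `[lo, hi]`, so every in-range value maps to exactly one bin;
#'   out-of-range values are a domain error (or are dropped, see
#'   [encode_transactions()]).
#' * `rule_threshold(cut)` -- two levels `<=cut` / `>cut` (rendered with a
#'   Unicode `≤` so labels stay `=`-free).
#'
#' @param recode optional named character vector `c(raw = label)`.
#' @param strip optional regex removed from raw values before recoding.
#' @param lo,hi closed reference-range bounds, `lo < hi`.
#' @param breaks increasing numeric vector of bin edges (length >= 2).
#' @param labels optional bin labels; defaults to `"lo-hi"`.
#' @param cut numeric threshold.
#' @return A `disc_rule` object.
#' @name disc_rules
NULL

#' @rdname disc_rules
#' @export
rule_categorical <- function(recode = NULL, strip = NULL) {
  structure(list(type = "categorical", recode = recode, strip = strip),
            class = "disc_rule")
}

#' @rdname disc_rules
#' @export
rule_boolean <- function() {
  structure(list(type = "boolean"), class = "disc_rule")
}

#' @rdname disc_rules
#' @export
rule_normal_range <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  structure(list(type = "normal_range", lo = lo, hi = hi), class = "disc_rule")
}

#' @rdname disc_rules
#' @export
rule_bins <- function(breaks, labels = NULL) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2, !is.unsorted(breaks, strictly = TRUE))
  k <- length(breaks) - 1
  if (is.null(labels)) {
    labels <- paste0(breaks[-length(breaks)], "-", breaks[-1])
  }
  stopifnot(length(labels) == k, !anyDuplicated(labels))
  structure(list(type = "bins", breaks = breaks, labels = labels),
            class = "disc_rule")
}

#' @rdname disc_rules
#' @export
rule_threshold <- function(cut, labels = NULL) {
  stopifnot(is.numeric(cut), length(cut) == 1)
  if (is.null(labels)) labels <- c(paste0("≤", cut), paste0(">", cut))
  stopifnot(length(labels) == 2)
  structure(list(type = "threshold", cut = cut, labels = labels),
            class = "disc_rule")
}

#' Build a discretization spec
#'
#' @param rules named list of `disc_rule` objects, one entry per attribute.
#' @return A `disc_spec` object.
#' @export
disc_spec <- function(rules) {
  stopifnot(is.list(rules), !is.null(names(rules)), all(nzchar(names(rules))),
            !anyDuplicated(names(rules)))
  ok <- vapply(rules, inherits, logical(1), what = "disc_rule")
  if (!all(ok)) stop("all entries must be disc_rule objects", call. = FALSE)
  structure(rules, class = "disc_spec")
}

BOOL_MAP <- c(f = "False", t = "True", "0" = "False", "1" = "True",
              n = "False", y = "True", no = "False", yes = "True",
              false = "False", true = "True")

as_num_or_die <- function(attr, values) {
  suppressWarnings(num <- as.numeric(values))
  bad <- is.na(num) & !is.na(values)
  if (any(bad)) {
    stop(sprintf("attribute '%s': non-numeric value '%s' under a numeric rule",
                 attr, values[which(bad)[1]]), call. = FALSE)
  }
  num
}

# Vectorized rule application; returns labels, NA_character_ where the value
# falls outside every bin (callers decide whether that is an error).
apply_rule <- function(rule, attr, values) {
  values <- as.character(values)
  switch(rule$type,
    categorical = {
      v <- trimws(values)
      if (!is.null(rule$strip)) v <- sub(rule$strip, "", v)
      if (!is.null(rule$recode)) {
        hit <- match(v, names(rule$recode))
        unknown <- is.na(hit) & !is.na(v)
        if (any(unknown)) {
          stop(sprintf("attribute '%s': unmapped category '%s'",
                       attr, v[which(unknown)[1]]), call. = FALSE)
        }
        v[!is.na(hit)] <- unname(rule$recode[hit[!is.na(hit)]])
      }
      v
    },
    boolean = {
      v <- tolower(trimws(values))
      hit <- match(v, names(BOOL_MAP))
      unknown <- is.na(hit) & !is.na(v)
      if (any(unknown)) {
        stop(sprintf("attribute '%s': unrecognized boolean value '%s'",
                     attr, values[which(unknown)[1]]), call. = FALSE)
      }
      out <- rep(NA_character_, length(v))
      out[!is.na(hit)] <- unname(BOOL_MAP[hit[!is.na(hit)]])
      out
    },
    normal_range = {
      num <- as_num_or_die(attr, values)
      ifelse(is.na(num), NA_character_,
             ifelse(num >= rule$lo & num <= rule$hi, "Normal", "Abnormal"))
    },
    bins = {
      num <- as_num_or_die(attr, values)
      # [lo, hi) bins, last bin closed on the right
      idx <- findInterval(num, rule$breaks, rightmost.closed = TRUE)
      idx[!is.na(num) & (idx < 1 | idx > length(rule$labels))] <- NA_integer_
      rule$labels[idx]
    },
    threshold = {
      num <- as_num_or_die(attr, values)
      ifelse(is.na(num), NA_character_,
             ifelse(num <= rule$cut, rule$labels[1], rule$labels[2]))
    },
    stop("unknown rule type: ", rule$type, call. = FALSE)
  )
}

#' Discretize a single raw value
#'
#' Deterministically maps one raw value of one attribute to its rendered item.
#' Reference ranges use closed intervals; values outside every bin of a
#' binning rule raise a domain error naming the attribute and value.
#'
#' @param attr attribute name.
#' @param value a single non-missing raw value (string or number).
#' @param spec a [disc_spec()] containing a rule for `attr`.
#' @return The rendered item string `"attr=level"`.
#' @export
#' @examples
#' sp <- disc_spec(list(T3 = rule_normal_range(1.3, 3.1)))
#' discretize_value("T3", 5.0, sp)   # "T3=Abnormal"
discretize_value <- function(attr, value, spec) {
  stopifnot(inherits(spec, "disc_spec"), length(value) == 1)
  if (is.na(value)) stop("value is missing; clean the table first", call. = FALSE)
  rule <- spec[[attr]]
  if (is.null(rule)) stop("no discretization rule for attribute: ", attr, call. = FALSE)
  lab <- apply_rule(rule, attr, value)
  if (is.na(lab)) {
    stop(sprintf("attribute '%s': value '%s' falls outside every bin",
                 attr, as.character(value)), call. = FALSE)
  }
  make_item(attr, lab)
}

#' Encode a cleaned table as a transaction database
#'
#' Applies the discretization spec column-wise and emits one transaction per
#' record: exactly one `"attr=level"` item per attribute, one of which is the
#' class item.
#'
#' @param raw a cleaned raw table (no missing values) whose columns all have
#'   rules in `spec`.
#' @param spec a [disc_spec()].
#' @param class_attr name of the class attribute.
#' @param out_of_range `"error"` (default) stops on a value outside a binning
#'   rule's bins, naming attribute, value and record; `"drop"` removes such
#'   records and reports the dropped count via attribute `n_out_of_range` and
#'   a message.
#' @return A [transaction_db()] with `class_attr` set.
#' @export
encode_transactions <- function(raw, spec, class_attr,
                                out_of_range = c("error", "drop")) {
  out_of_range <- match.arg(out_of_range)
  stopifnot(inherits(spec, "disc_spec"))
  if (!class_attr %in% colnames(raw)) {
    stop("class attribute not in table: ", class_attr, call. = FALSE)
  }
  missing_rules <- setdiff(colnames(raw), names(spec))
  if (length(missing_rules) > 0) {
    stop("no discretization rule for attribute(s): ",
         paste(missing_rules, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0) {
    db <- transaction_db(list(), class_attr = class_attr,
                         label = attr(raw, "source_label"))
    attr(db, "n_out_of_range") <- 0L
    return(db)
  }
  labels <- matrix(NA_character_, nrow = n, ncol = ncol(raw),
                   dimnames = list(NULL, colnames(raw)))
  for (attr_name in colnames(raw)) {
    vals <- raw[[attr_name]]
    if (anyNA(vals)) {
      stop(sprintf("attribute '%s' still contains missing values at record %d; run drop_incomplete() first",
                   attr_name, which(is.na(vals))[1]), call. = FALSE)
    }
    labels[, attr_name] <- apply_rule(spec[[attr_name]], attr_name, vals)
  }
  bad <- which(rowSums(is.na(labels)) > 0)
  if (length(bad) > 0) {
    if (out_of_range == "error") {
      i <- bad[1]
      j <- which(is.na(labels[i, ]))[1]
      stop(sprintf("record %d, attribute '%s': value '%s' falls outside every bin",
                   i, colnames(labels)[j], as.character(raw[[j]][i])),
           call. = FALSE)
    }
    message(length(bad), " record(s) dropped: value outside every bin")
    labels <- labels[-bad, , drop = FALSE]
  }
  items <- lapply(seq_len(nrow(labels)), function(i) {
    mapply(make_item, colnames(labels), labels[i, ], USE.NAMES = FALSE)
  })
  db <- transaction_db(items, class_attr = class_attr,
                       label = attr(raw, "source_label"))
  attr(db, "n_out_of_range") <- length(bad)
  db
}

#' Stratify a transaction database by class
#'
#' Splits the database into one group per class level, in preparation for
#' class-stratified mining (healthy and sick groups analyzed separately).
#' Group sizes sum to the input size; within each group the class item is by
#' construction present in every transaction.
#'
#' @param db a [transaction_db()].
#' @param class_attr class attribute name; defaults to `db$class_attr`.
#' @return Named list of `transaction_db`, one per class level present.
#' @export
split_by_class <- function(db, class_attr = db$class_attr) {
  stopifnot(inherits(db, "transaction_db"), !is.null(class_attr))
  lvl <- vapply(db$transactions, function(txn) {
    hits <- txn[item_attr(txn) == class_attr]
    if (length(hits) != 1) {
      stop("transaction lacks a unique class item for attribute: ", class_attr,
           call. = FALSE)
    }
    split_item(hits)[["level"]]
  }, character(1))
  out <- lapply(split(seq_len(db$N), lvl), function(idx) {
    g <- transaction_db(db$transactions[idx], class_attr = class_attr,
                        label = db$label)
    g
  })
  out[sort(names(out))]
}

#' Bundled discretization presets
#'
#' `spec_dataset1()` encodes the thyroid "sick" database design: six decade
#' age bins spanning 20--80, sex, thirteen boolean history/comorbidity flags,
#' five thyroid-function laboratory values discretized against their reference
#' ranges (TSH 0.27--4.2, T3 1.3--3.1, TT4 62--164, T4U 0.7--1.8, FTI
#' 53--142, all closed intervals), and a Negative/Positive class.
#' `spec_dataset2()` encodes the cardiovascular-records design: an age split
#' at 50, gender, twelve boolean comorbidity flags, and a Negative/Positive
#' thyroid-disease class.
#'
#' `dataset1_selection()` / `dataset2_selection()` return the matching
#' attribute selections: the source-file column names, the retained subset and
#' the rename map from source spellings to the canonical attribute names the
#' presets use.
#'
#' @return A [disc_spec()] (presets) or a list with `col_names`, `names`,
#'   `rename`, `class_attr` (selections).
#' @name presets
NULL

#' @rdname presets
#' @export
spec_dataset1 <- function() {
  bools <- c("On_thyroxine", "On_antithyroid_med", "Sick", "Pregnant",
             "Thyroid_surgery", "I131", "Query_hypothyroid",
             "Query_hyperthyroid", "Lithium", "Goiter", "Tumor",
             "Hypopituitary", "Psych")
  rules <- c(
    list(
      Age = rule_bins(seq(20, 80, by = 10)),
      Sex = rule_categorical(recode = c(M = "M", F = "F", m = "M", f = "F")),
      TSH = rule_normal_range(0.27, 4.2),
      T3  = rule_normal_range(1.3, 3.1),
      TT4 = rule_normal_range(62, 164),
      T4U = rule_normal_range(0.7, 1.8),
      FTI = rule_normal_range(53, 142),
      Class = rule_categorical(
        recode = c(negative = "Negative", sick = "Positive",
                   Negative = "Negative", Positive = "Positive"),
        strip = "[.|].*$"
      )
    ),
    stats::setNames(replicate(length(bools), rule_boolean(), simplify = FALSE),
                    bools)
  )
  disc_spec(rules)
}

#' @rdname presets
#' @export
spec_dataset2 <- function() {
  bools <- c("Diabetes_mellitus", "Hypertension", "Current_smoker",
             "Ex_smoker", "Obesity", "CRF", "CVA", "AD", "Edema", "LR",
             "Dyspnea", "CVD")
  rules <- c(
    list(
      Age = rule_threshold(50),
      Gender = rule_categorical(recode = c(M = "M", F = "F", Male = "M",
                                           Fmale = "F", Female = "F")),
      Thyroid_disease = rule_categorical(
        recode = c(N = "Negative", Y = "Positive",
                   Negative = "Negative", Positive = "Positive"))
    ),
    stats::setNames(replicate(length(bools), rule_boolean(), simplify = FALSE),
                    bools)
  )
  disc_spec(rules)
}

#' @rdname presets
#' @export
dataset1_selection <- function() {
  # column order of the distributed sick `.data` file (30 columns, no header)
  col_names <- c(
    "age", "sex", "on_thyroxine", "query_on_thyroxine",
    "on_antithyroid_medication", "sick", "pregnant", "thyroid_surgery",
    "I131_treatment", "query_hypothyroid", "query_hyperthyroid", "lithium",
    "goitre", "tumor", "hypopituitary", "psych", "TSH_measured", "TSH",
    "T3_measured", "T3", "TT4_measured", "TT4", "T4U_measured", "T4U",
    "FTI_measured", "FTI", "TBG_measured", "TBG", "referral_source", "class"
  )
  rename <- c(
    age = "Age", sex = "Sex", on_thyroxine = "On_thyroxine",
    on_antithyroid_medication = "On_antithyroid_med", sick = "Sick",
    pregnant = "Pregnant", thyroid_surgery = "Thyroid_surgery",
    I131_treatment = "I131", query_hypothyroid = "Query_hypothyroid",
    query_hyperthyroid = "Query_hyperthyroid", lithium = "Lithium",
    goitre = "Goiter", tumor = "Tumor", hypopituitary = "Hypopituitary",
    psych = "Psych", TSH = "TSH", T3 = "T3", TT4 = "TT4", T4U = "T4U",
    FTI = "FTI", class = "Class"
  )
  list(col_names = col_names, names = unname(rename), rename = rename,
       class_attr = "Class")
}

#' @rdname presets
#' @export
dataset2_selection <- function() {
  rename <- c(
    Age = "Age", Sex = "Gender", DM = "Diabetes_mellitus",
    HTN = "Hypertension", `Current Smoker` = "Current_smoker",
    `EX-Smoker` = "Ex_smoker", Obesity = "Obesity", CRF = "CRF", CVA = "CVA",
    `Airway disease` = "AD", Edema = "Edema", `Lung rales` = "LR",
    Dyspnea = "Dyspnea", CVD = "CVD", `Thyroid Disease` = "Thyroid_disease"
  )
  list(col_names = NULL, names = unname(rename), rename = rename,
       class_attr = "Thyroid_disease")
}
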