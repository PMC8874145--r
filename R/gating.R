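#' Gate geometry primitives
#'
#' A gate node combines one or more primitive conditions (AND): a one-sided
#' `threshold` on a channel, a `rectangle` on two channels, a `ratio_band`
#' on the ratio of two channels (doublet exclusion), or `any_of` (OR over
#' thresholds, e.g. "CD56+ and/or CD16+"). Thresholds are expressed in
#' linear units; because all conditions are monotone region tests, the
#' assignment is identical whether evaluated on linear or variance-
#' stabilized values.
#'
#' @param channel,cut,side threshold: events with `channel side cut` pass
#'   (`side` is `">="` or `"<"`, making sibling gates half-open and
#'   disjoint).
#' @return A condition list used by [gate_node()].
#' @export
g_threshold <- function(channel, cut, side = ">=") {
  stopifnot(side %in% c(">=", "<"))
  list(type = "threshold", channel = channel, cut = cut, side = side)
}

#' @rdname g_threshold
#' @param xchannel,xmin,xmax,ychannel,ymin,ymax rectangle bounds
#'   (half-open: `[min, max)`); use `Inf` for an unbounded side.
#' @export
g_rectangle <- function(xchannel, xmin, xmax, ychannel, ymin, ymax) {
  list(type = "rectangle", xchannel = xchannel, xmin = xmin, xmax = xmax,
       ychannel = ychannel, ymin = ymin, ymax = ymax)
}

#' @rdname g_threshold
#' @param num,den numerator/denominator channels of the ratio.
#' @param min,max inclusive-min, exclusive-max band on `num/den`.
#' @export
g_ratio_band <- function(num, den, min, max) {
  list(type = "ratio_band", num = num, den = den, min = min, max = max)
}

#' @rdname g_threshold
#' @param conditions list of threshold conditions; an event passes when any
#'   of them does.
#' @export
g_any <- function(conditions) {
  list(type = "any_of", conditions = conditions)
}

#' @rdname g_threshold
#' @param name node name (leaf names become population codes).
#' @param gate list of conditions (AND); `NULL` for a pass-through node.
#' @param children list of child `gate_node`s. Siblings are evaluated in
#'   order with first-match capture, so overlapping sibling definitions
#'   (e.g. Tfh before the CD45RA/CD27 quadrants) stay disjoint; for
#'   geometrically disjoint siblings the order is irrelevant.
#' @export
gate_node <- function(name, gate = NULL, children = list()) {
  structure(list(name = name, gate = gate, children = children),
            class = "gate_node")
}

eval_condition <- function(cond, exprs) {
  need <- function(ch) {
    if (!ch %in% colnames(exprs)) {
      stop(sprintf("gating channel '%s' missing from event table", ch),
           call. = FALSE)
    }
    exprs[, ch]
  }
  switch(cond$type,
    threshold = {
      x <- need(cond$channel)
      if (cond$side == ">=") x >= cond$cut else x < cond$cut
    },
    rectangle = {
      x <- need(cond$xchannel); y <- need(cond$ychannel)
      x >= cond$xmin & x < cond$xmax & y >= cond$ymin & y < cond$ymax
    },
    ratio_band = {
      r <- need(cond$num) / need(cond$den)
      r >= cond$min & r < cond$max
    },
    any_of = {
      hit <- rep(FALSE, nrow(exprs))
      for (c2 in cond$conditions) hit <- hit | eval_condition(c2, exprs)
      hit
    },
    stop(sprintf("unknown gate geometry '%s'", cond$type), call. = FALSE)
  )
}

eval_gate <- function(gate, exprs, members) {
  if (is.null(gate)) return(members)
  for (cond in gate) members <- members & eval_condition(cond, exprs)
  members
}

#' Gating template
#'
#' A tube's hierarchical gating tree: a root [gate_node()] whose leaves are
#' the reported subsets.
#'
#' @param tube_id `"innate"` or `"adaptive"` (or any identifier).
#' @param root root `gate_node`.
#' @param channel_dependencies optional named list: when the named channel
#'   is absent from a panel, the listed leaf codes become unavailable even
#'   though their own geometry does not reference it (negatively defined
#'   subsets).
#' @return A `gating_template`.
#' @export
gating_template <- function(tube_id, root, channel_dependencies = list()) {
  tpl <- structure(list(tube_id = tube_id, root = root,
                        channel_dependencies = channel_dependencies),
                   class = "gating_template")
  lv <- list_leaves(tpl)
  if (anyDuplicated(lv)) {
    stop(sprintf("duplicate leaf name(s): %s",
                 paste(unique(lv[duplicated(lv)]), collapse = ", ")),
         call. = FALSE)
  }
  tpl
}

#' @export
print.gating_template <- function(x, ...) {
  cat(sprintf("gating_template '%s': %d leaf subsets\n", x$tube_id,
              length(list_leaves(x))))
  cat(paste(list_leaves(x), collapse = ", "), "\n")
  invisible(x)
}

#' List the leaf population codes of a template
#'
#' @param template a [gating_template()].
#' @return Ordered character vector of leaf codes (tree order).
#' @export
list_leaves <- function(template) {
  stopifnot(inherits(template, "gating_template"))
  walk <- function(node) {
    if (length(node$children) == 0) return(node$name)
    unlist(lapply(node$children, walk))
  }
  walk(template$root)
}

# channels referenced by a node's own gate
gate_channels <- function(gate) {
  if (is.null(gate)) return(character(0))
  unique(unlist(lapply(gate, function(cond) {
    switch(cond$type,
      threshold = cond$channel,
      rectangle = c(cond$xchannel, cond$ychannel),
      ratio_band = c(cond$num, cond$den),
      any_of = unlist(lapply(cond$conditions, function(c2) c2$channel)))
  })))
}

#' Apply a gating template to an event table
#'
#' Events failing an ancestor gate are unassigned (`NA`), not errors.
#' Within a sibling set, events are captured by the first matching gate, so
#' every event maps to at most one leaf. Debris and doublet exclusion are
#' ordinary nodes at the top of both built-in templates.
#'
#' @param table a compensated [event_table] containing every template
#'   channel.
#' @param template a [gating_template()].
#' @return A `gate_result`: list with `assignment` (per-event leaf code or
#'   `NA`), `counts` (data frame: node, parent, n, n_unassigned — events
#'   stopping at that node), and `leaves`.
#' @export
apply_template <- function(table, template) {
  stopifnot(inherits(table, "event_table"),
            inherits(template, "gating_template"))
  all_ch <- unique(unlist(collect_channels(template$root)))
  missing <- setdiff(all_ch, channels(table))
  if (length(missing)) {
    stop(sprintf("template/panel mismatch: channel(s) %s missing",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  exprs <- table$exprs
  n <- nrow(exprs)
  assignment <- rep(NA_character_, n)
  counts <- list()
  recurse <- function(node, members, parent) {
    inside <- eval_gate(node$gate, exprs, members)
    n_inside <- sum(inside)
    if (length(node$children) == 0) {
      assignment[inside] <<- node$name
      counts[[length(counts) + 1]] <<- data.frame(
        node = node$name, parent = parent, n = n_inside, n_unassigned = 0L)
      return(invisible(NULL))
    }
    pool <- inside
    captured <- 0L
    for (child in node$children) {
      child_in <- eval_gate(child$gate, exprs, pool)
      recurse_child_count <- sum(child_in)
      # first-match capture: later siblings see the remaining pool
      recurse(modifyList(child, list(gate = NULL)) |> structure(class = "gate_node"),
              child_in, node$name)
      pool <- pool & !child_in
      captured <- captured + recurse_child_count
    }
    counts[[length(counts) + 1]] <<- data.frame(
      node = node$name, parent = parent, n = n_inside,
      n_unassigned = n_inside - captured)
    invisible(NULL)
  }
  recurse(template$root, rep(TRUE, n), NA_character_)
  counts <- do.call(rbind, counts)
  rownames(counts) <- NULL
  structure(list(assignment = assignment, counts = counts,
                 leaves = list_leaves(template), tube_id = template$tube_id),
            class = "gate_result")
}

collect_channels <- function(node) {
  c(list(gate_channels(node$gate)), lapply(node$children, collect_channels))
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("gate_result (%s): %d events, %d leaves\n", x$tube_id,
              length(x$assignment), length(x$leaves)))
  tb <- table(factor(x$assignment, levels = x$leaves))
  print(tb)
  invisible(x)
}

#' Validate a template against a panel
#'
#' Reports unknown channels (and the leaves they make unavailable),
#' duplicate leaf names, and unreachable nodes. Negatively defined subsets
#' listed in the template's `channel_dependencies` are additionally flagged
#' when their supporting channel is absent — e.g. in a reduced innate panel
#' without the CD56 detection channel ILC-1 cannot be separated from
#' CD56+CD16- NK cells and is reported unavailable, while leaves whose
#' `any_of` geometry retains an available alternative (NK via CD16) stay
#' usable.
#'
#' @param template a [gating_template()].
#' @param panel character vector of available channel names.
#' @return A data frame with columns `type` (`unknown_channel`,
#'   `leaf_unavailable`, `leaf_degraded`, `duplicate_leaf`), `item`,
#'   `message`; zero rows when the panel fully supports the template.
#' @export
validate_template <- function(template, panel) {
  stopifnot(inherits(template, "gating_template"))
  issues <- list()
  add <- function(type, item, message) {
    issues[[length(issues) + 1]] <<- data.frame(type = type, item = item,
                                                message = message)
  }
  lv <- list_leaves(template)
  if (anyDuplicated(lv)) {
    for (d in unique(lv[duplicated(lv)])) {
      add("duplicate_leaf", d, "leaf name occurs more than once")
    }
  }
  walk <- function(node, ancestors_missing) {
    own <- gate_channels(node$gate)
    miss <- setdiff(own, panel)
    for (ch in miss) {
      add("unknown_channel", ch,
          sprintf("node '%s' references channel '%s' not in the panel",
                  node$name, ch))
    }
    # an any_of gate survives if at least one alternative channel remains
    degraded_only <- FALSE
    if (length(miss) && !is.null(node$gate)) {
      blocking <- character(0)
      for (cond in node$gate) {
        chs <- gate_channels(list(cond))
        lost <- setdiff(chs, panel)
        if (length(lost)) {
          if (cond$type == "any_of" && length(setdiff(chs, lost)) > 0) {
            degraded_only <- TRUE
          } else {
            blocking <- c(blocking, lost)
          }
        }
      }
      miss <- unique(blocking)
    }
    unavailable <- ancestors_missing || length(miss) > 0
    if (length(node$children) == 0) {
      if (unavailable) {
        add("leaf_unavailable", node$name,
            "gating path references channels absent from the panel")
      } else if (degraded_only) {
        add("leaf_degraded", node$name,
            "gate falls back to remaining any_of channel(s)")
      }
    }
    for (child in node$children) walk(child, unavailable)
  }
  walk(template$root, FALSE)
  for (ch in names(template$channel_dependencies)) {
    if (!ch %in% panel) {
      for (leaf in template$channel_dependencies[[ch]]) {
        add("leaf_unavailable", leaf,
            sprintf("subset cannot be resolved without channel '%s'", ch))
      }
    }
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(type = character(0), item = character(0),
               message = character(0))
  rownames(out) <- NULL
  out
}

#' Built-in innate-tube gating template
#'
#' Debris (low FSC) and doublets (FSC-A/FSC-H ratio outside the singlet
#' band) are excluded first, then CD45+ CD3- CD19- innate cells branch on
#' side scatter: neutrophils (SSC high, CD16+) and eosinophils (SSC very
#' high, CD16-); within SSC low/med, CD123+ cells split into basophils
#' (HLA-DR-) and pDC (HLA-DR+); CD123- HLA-DR+ CD11c+ cells yield mDC
#' (CD14- CD16- HLA-DR bright) and the CD14/CD16 monocyte split; CD123-
#' HLA-DR- CD14- lymphoid (SSC very low) events split into CD127+ CD16-
#' ILCs (CRTH2/CD117 quadrants) and CD127- NK cells (CD56+ and/or CD16+).
#'
#' @param cuts named list of cut values, see [default_gate_cuts()].
#' @return A [gating_template()] with 12 leaves.
#' @export
innate_template <- function(cuts = default_gate_cuts()) {
  p <- function(ch) g_threshold(ch, cuts$fl_pos, ">=")
  n <- function(ch) g_threshold(ch, cuts$fl_pos, "<")
  ilc <- gate_node("ILC", list(p("CD127"), n("CD16")), list(
    gate_node("ILC-2", list(p("CRTH2"), n("CD117"))),
    gate_node("ILC-3", list(n("CRTH2"), p("CD117"))),
    gate_node("ILC-1", list(n("CRTH2"), n("CD117")))
  ))
  nk <- gate_node("NK cells", list(
    g_threshold("CD127", cuts$fl_pos, "<"),
    g_any(list(p("CD56"), p("CD16")))
  ))
  lymphoid <- gate_node(
    "Lymphoid (SSC very low)",
    list(g_threshold("SSC-A", cuts$ssc_vlow, "<"), n("CD14")),
    list(ilc, nk))
  monos <- gate_node("Monocytes & mDC", list(p("HLA-DR"), p("CD11c")), list(
    gate_node("mDC", list(n("CD14"), n("CD16"),
                          g_threshold("HLA-DR", cuts$hladr_high, ">="))),
    gate_node("class Mono", list(p("CD14"), n("CD16"))),
    gate_node("inter Mono", list(p("CD14"), p("CD16"))),
    gate_node("nonc Mono", list(n("CD14"), p("CD16")))
  ))
  cd123neg <- gate_node("CD123-", list(n("CD123")), list(
    monos,
    gate_node("HLA-DR-", list(n("HLA-DR")), list(lymphoid))
  ))
  cd123pos <- gate_node("CD123+", list(p("CD123")), list(
    gate_node("Basophils", list(n("HLA-DR"))),
    gate_node("pDC", list(p("HLA-DR")))
  ))
  ssc_lowmed <- gate_node(
    "SSC low/med", list(g_threshold("SSC-A", cuts$ssc_high, "<")),
    list(cd123pos, cd123neg))
  innate_cells <- gate_node("CD45+ CD3- CD19-",
                            list(p("CD45"), n("CD3"), n("CD19")), list(
    gate_node("Neutrophils",
              list(g_rectangle("SSC-A", cuts$ssc_high, cuts$ssc_vhigh,
                               "CD16", cuts$fl_pos, Inf))),
    gate_node("Eosinophils",
              list(g_threshold("SSC-A", cuts$ssc_vhigh, ">="), n("CD16"))),
    ssc_lowmed
  ))
  root <- gate_node("All events", NULL, list(
    gate_node("Non-debris",
              list(g_threshold("FSC-A", cuts$fsc_debris, ">=")), list(
      gate_node("Singlets",
                list(g_ratio_band("FSC-A", "FSC-H", cuts$singlet_min,
                                  cuts$singlet_max)),
                list(innate_cells))
    ))
  ))
  gating_template("innate", root,
                  channel_dependencies = list(CD56 = "ILC-1"))
}

#' Built-in adaptive-tube gating template
#'
#' After debris/doublet exclusion, CD45+ SSC-low lymphocytes split into
#' CD3+ CD19- T cells (TCRgd+ first, then CD4/CD8 branches; within CD4,
#' Tfh (CXCR5+ CD45RA-) and Treg (CD25+ CD127-) are captured before the
#' CD45RA/CD27 quadrants) and CD3- CD19+ B cells (IgD/CD27 quadrants).
#'
#' @param cuts named list of cut values, see [default_gate_cuts()].
#' @return A [gating_template()] with 15 leaves.
#' @export
adaptive_template <- function(cuts = default_gate_cuts()) {
  p <- function(ch) g_threshold(ch, cuts$fl_pos, ">=")
  n <- function(ch) g_threshold(ch, cuts$fl_pos, "<")
  quadrants <- function(prefix) {
    list(
      gate_node(paste(prefix, "naive"), list(p("CD45RA"), p("CD27"))),
      gate_node(paste(prefix, "CM"), list(n("CD45RA"), p("CD27"))),
      gate_node(paste(prefix, "EM"), list(n("CD45RA"), n("CD27"))),
      gate_node(paste(prefix, "TEMRA"), list(p("CD45RA"), n("CD27")))
    )
  }
  cd4 <- gate_node("CD4", list(p("CD4"), n("CD8")), c(
    list(gate_node("Tfh", list(p("CXCR5"), n("CD45RA"))),
         gate_node("Treg", list(p("CD25"), n("CD127")))),
    quadrants("CD4")
  ))
  cd8 <- gate_node("CD8", list(p("CD8"), n("CD4")), quadrants("CD8"))
  tcells <- gate_node("T cells", list(p("CD3"), n("CD19")), list(
    gate_node("Tgd", list(p("TCRgd"))),
    gate_node("TCRab", list(n("TCRgd")), list(cd4, cd8))
  ))
  bcells <- gate_node("B cells", list(n("CD3"), p("CD19")), list(
    gate_node("B naive", list(p("IgD"), n("CD27"))),
    gate_node("B nat Eff", list(p("IgD"), p("CD27"))),
    gate_node("B sw Mem", list(n("IgD"), p("CD27"))),
    gate_node("B dn", list(n("IgD"), n("CD27")))
  ))
  lymph <- gate_node("Lymphocytes",
                     list(p("CD45"),
                          g_threshold("SSC-A", cuts$ssc_vlow, "<")),
                     list(tcells, bcells))
  root <- gate_node("All events", NULL, list(
    gate_node("Non-debris",
              list(g_threshold("FSC-A", cuts$fsc_debris, ">=")), list(
      gate_node("Singlets",
                list(g_ratio_band("FSC-A", "FSC-H", cuts$singlet_min,
                                  cuts$singlet_max)),
                list(lymph))
    ))
  ))
  gating_template("adaptive", root)
}

#' Serialize / deserialize gating templates as JSON
#'
#' @param template a [gating_template()].
#' @param path JSON file path.
#' @return `template_to_json()` writes and returns `path`;
#'   `template_from_json()` returns the template.
#' @export
template_to_json <- function(template, path) {
  stopifnot(inherits(template, "gating_template"))
  strip <- function(node) {
    list(name = node$name, gate = node$gate,
         children = lapply(node$children, strip))
  }
  obj <- list(tube_id = template$tube_id, root = strip(template$root),
              channel_dependencies = template$channel_dependencies)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname template_to_json
#' @export
template_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rebuild <- function(node) {
    gate <- node$gate
    if (!is.null(gate)) {
      gate <- lapply(gate, function(cond) {
        cond <- lapply(cond, function(v) {
          if (identical(v, "Inf")) Inf else if (identical(v, "-Inf")) -Inf
          else v
        })
        if (!is.null(cond$conditions)) {
          cond$conditions <- lapply(cond$conditions, function(c2) c2)
        }
        cond
      })
    }
    gate_node(node$name, gate, lapply(node$children, rebuild))
  }
  deps <- lapply(obj$channel_dependencies, function(x) unlist(x))
  gating_template(obj$tube_id, rebuild(obj$root),
                  channel_dependencies = deps)
}

#' Reference background cutoffs for the 27 leukocyte subsets
#'
#' The per-subset FMO background cutoffs (ABC units) established on the
#' multicenter standardization dataset, distributed with the package as the
#' reference input to [summarize_resolution()].
#'
#' @return Data frame with `code` (leaf population code), `tube` and
#'   `cutoff_abc`, one row per subset (12 innate + 15 adaptive).
#' @export
reference_background_cutoffs <- function() {
  data.frame(
    code = c("Neutrophils", "Eosinophils", "Basophils", "class Mono",
             "inter Mono", "nonc Mono", "mDC", "pDC", "ILC-1", "ILC-2",
             "ILC-3", "NK cells",
             "Tgd", "CD4 naive", "CD4 CM", "CD4 EM", "CD4 TEMRA", "Treg",
             "Tfh", "CD8 naive", "CD8 CM", "CD8 EM", "CD8 TEMRA",
             "B naive", "B dn", "B nat Eff", "B sw Mem"),
    tube = rep(c("innate", "adaptive"), c(12, 15)),
    cutoff_abc = c(408, 632, 357, 384, 353, 350, 396, 309, 336, 312, 459,
                   229,
                   461, 369, 471, 406, 360, 305, 415, 384, 425, 396, 338,
                   773, 732, 786, 727),
    stringsAsFactors = FALSE
  )
}
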