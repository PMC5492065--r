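# Shared constants: stage/state/category layouts and allowed transitions.
# Collated first (file name) so every other file can use them at load time.

STAGES <- c("egg", "I1", "I2", "I3", "I4", "I5", "pupa")
N_STAGES <- 7L
N_STATES <- 15L
STATE_NAMES <- c(STAGES, paste0("nd_", STAGES), "dead")

# observation categories: not seen, seen alive in each stage, corpse of each
# stage.  Corpse categories for egg and pupa exist to keep PO square but can
# never receive probability mass (their detection is fixed at zero).
CATEGORIES <- c("NS", paste0("seen_", STAGES), paste0("dead_", STAGES))
N_CATEGORIES <- 15L

# Allowed growth destinations conditional on survival.  Eggs hatch into I1;
# early instars (I1-I3) can molt one or two stages in a 3-day step; I4 can
# only reach I5; I5 pupates; the pupa is terminal within this model because
# adult emergence is not observed.
GROWTH_DESTS <- list(
  egg  = "I1",
  I1   = c("I2", "I3"),
  I2   = c("I3", "I4"),
  I3   = c("I4", "I5"),
  I4   = "I5",
  I5   = "pupa",
  pupa = character(0)
)


# file-format observation categories -> internal category index (1..15);
# corpses of eggs (9) and pupae (15) are internal-only and never occur in
# data files
FILE_CATEGORY_INDEX <- c(NS = 1L, E = 2L, L1 = 3L, L2 = 4L, L3 = 5L,
                         L4 = 6L, L5 = 7L, P = 8L,
                         D1 = 10L, D2 = 11L, D3 = 12L, D4 = 13L, D5 = 14L)

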