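{
  "version": "1",
  "comment": "Tiered extraction rules for smoking-behavior quantities and cessation cues. Patterns are case-insensitive Perl regexes; NUM in a pattern is expanded by the loader to digits-or-word-number alternation. Each pattern captures its quantity in group 1 unless fixed_value is given. Tier order (pack_years, packs_per_day, cigarettes_per_day, years_smoked) is the evaluation order; a complete pack-year match short-circuits the lower tiers.",
  "word_numbers": {
    "half": 0.5, "one": 1, "two": 2, "three": 3, "four": 4, "five": 5,
    "six": 6, "seven": 7, "eight": 8, "nine": 9, "ten": 10
  },
  "pack_years": [
    {"pattern": "\\b(NUM)\\s*\\+?\\s*(?:pack|pk)[\\s-]*(?:year|yr)s?\\b"},
    {"pattern": "\\b(?:pack|pk)[\\s-]*(?:year|yr)s?\\s*(?:history|hx)?\\s*(?:of|:|=)\\s*(NUM)\\b"}
  ],
  "packs_per_day": [
    {"pattern": "\\b(NUM)\\s*(?:a\\s+)?(?:packs?|pks?)\\s*(?:per|a|each|/)\\s*(?:day|d)\\b"},
    {"pattern": "\\b(NUM)\\s*ppd\\b"},
    {"pattern": "\\b(?:a|one)\\s+pack\\s+(?:per|a|each)\\s+day\\b", "fixed_value": 1},
    {"pattern": "\\bhalf\\s+(?:a\\s+|an?\\s+)?pack\\s*(?:per|a|each|/)\\s*day\\b", "fixed_value": 0.5}
  ],
  "cigarettes_per_day": [
    {"pattern": "\\b(NUM)\\s*(?:cigarettes?|cigs?)\\s*(?:per|a|each|/)\\s*(?:day|d)\\b"},
    {"pattern": "\\b(NUM)\\s*(?:cigarettes?|cigs?)\\s*daily\\b"},
    {"pattern": "\\b(NUM)\\s*cpd\\b"}
  ],
  "years_smoked": [
    {"pattern": "\\bfor\\s+(?:the\\s+past\\s+|about\\s+|over\\s+)?(NUM)\\s*(?:years?|yrs?)\\b(?!\\s*ago)"},
    {"pattern": "\\b(?:x|times)\\s*(NUM)\\s*(?:years?|yrs?)\\b(?!\\s*ago)"},
    {"pattern": "\\bsmok\\w*\\s+(?:for\\s+)?(NUM)\\s*(?:years?|yrs?)\\b(?!\\s*ago)"},
    {"pattern": "\\b(NUM)[\\s-]*(?:year|yr)\\s+(?:smoking\\s+)?(?:history|hx)\\b"},
    {"pattern": "\\b(NUM)\\s*(?:years?|yrs?)\\s+of\\s+(?:smoking|tobacco\\s+use)\\b"}
  ],
  "cessation_cues": [
    "\\bquit(?:ting|s)?\\b",
    "\\bstop(?:ped|s)?\\s+(?:smoking|using\\s+tobacco|tobacco|cigarettes)\\b",
    "\\b(?:smoking|tobacco)\\s+cessation\\b",
    "\\bgave\\s+up\\s+(?:smoking|tobacco|cigarettes)\\b",
    "\\b(?:smoke|tobacco)[\\s-]*free\\s+since\\b",
    "\\blast\\s+(?:cigarette|smoked)\\b"
  ],
  "cue_negators": "\\b(?:denies|denied|no|not|never|without)\\b[\\s\\w]{0,15}$"
}
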