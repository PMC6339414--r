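# Cue lexicons for qualifier, course and assertion resolution.
# Cues are matched token-wise (multi-word cues as token sequences) within the
# sentence containing a term match, inside `window` tokens of the match.
window: 5
negation_cues: ["no", "denies", "without", "not", "never"]
ability_cues:
  able: ["able", "can", "independent", "independently", "unassisted", "steady"]
  with-difficulty: ["difficulty", "assist", "assisted", "needs help", "with help", "supervision", "unsteady"]
  unable: ["unable", "cannot", "dependent"]
frequency_cues:
  high-frequency: ["always", "daily", "often", "constant", "constantly"]
  mid-frequency: ["sometimes", "occasionally", "intermittent"]
  absent: ["never", "denies", "no"]
course_cues:
  chronic: ["chronic", "longstanding", "long-standing"]
  short-duration: ["brief", "transient"]
  sudden-onset: ["sudden", "acute", "abrupt"]
sentence_breaks: [".", ";", "\n"]
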