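{
  "tablet": "\\b(tab|tabs|tablet|tablets|chew|chewable|chews)\\b",
  "injectable": "\\b(inj|injection|injectable|vial|amp|ampoule)\\b",
  "spot_on": "spot[ -]?on|pipette",
  "oral_liquid": "\\b(susp|suspension|oral solution|liquid|syrup|drops)\\b"
}
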