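# MAIA (32-item, version 1) item map: eight subscales, 0-5 response scale,
# subscale = mean of items, items 5-9 reverse-coded.
instrument: MAIA
range: [0, 5]
aggregate: mean
reverse: [item05, item06, item07, item08, item09]
subscales:
  M1: [item01, item02, item03, item04]                     # Noticing
  M2: [item05, item06, item07]                             # Not-Distracting
  M3: [item08, item09, item10]                             # Not-Worrying
  M4: [item11, item12, item13, item14, item15, item16, item17]  # Attention Regulation
  M5: [item18, item19, item20, item21, item22]             # Emotional Awareness
  M6: [item23, item24, item25, item26]                     # Self-Regulation
  M7: [item27, item28, item29]                             # Body Listening
  M8: [item30, item31, item32]                             # Trusting
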