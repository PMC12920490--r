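# BPQ 22-item three-factor map: body awareness (BOA), supradiaphragmatic
# reactivity (SUP) and subdiaphragmatic/body awareness (BOA_SUB); 1-5
# response scale, subscale = item sum. NOTE: this item-to-factor assignment
# is a synthetic editable default -- replace the item lists with the factor
# structure of the BPQ version actually administered.
instrument: BPQ
range: [1, 5]
aggregate: sum
reverse: []
subscales:
  BOA: [item01, item02, item03, item04, item05, item06,
        item07, item08, item09, item10, item11, item12]
  SUP: [item13, item14, item15, item16, item17, item18]
  BOA_SUB: [item19, item20, item21, item22]
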