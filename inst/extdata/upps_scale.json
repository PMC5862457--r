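{
  "dimensions": {
    "negative_urgency": ["i2", "i7", "i12", "i17", "i22", "i29", "i34", "i39", "i44", "i50", "i53", "i58"],
    "lack_of_premeditation": ["i1", "i6", "i11", "i16", "i21", "i28", "i33", "i38", "i43", "i48", "i55"],
    "lack_of_perseverance": ["i4", "i9", "i14", "i19", "i24", "i27", "i32", "i37", "i42", "i47"],
    "sensation_seeking": ["i3", "i8", "i13", "i18", "i23", "i26", "i31", "i36", "i41", "i46", "i51", "i56"],
    "positive_urgency": ["i5", "i10", "i15", "i20", "i25", "i30", "i35", "i40", "i45", "i49", "i52", "i54", "i57", "i59"]
  },
  "short_form": {
    "negative_urgency": ["i29", "i34", "i44", "i50"],
    "lack_of_premeditation": ["i6", "i33", "i43", "i48"],
    "lack_of_perseverance": ["i4", "i27", "i37", "i42"],
    "sensation_seeking": ["i3", "i23", "i31", "i41"],
    "positive_urgency": ["i40", "i45", "i49", "i52"]
  },
  "reverse_keyed": [],
  "n_categories": [5]
}
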