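# Class-set definitions for the five basic classifiers.
# S1-S4 partition the eight ethogram codes into groups (a group label is the
# concatenation of its member codes); S5 enumerates the lumped class pairs.
version: 1
sets:
  S1: ["1", "2", "3", "4", "5", "6", "7", "8"]
  S2: ["12", "34", "5", "678"]
  S3: ["13", "24", "5", "678"]
  S4: ["5", "1234", "678"]
  S5: ["11", "15", "18", "22", "24", "28", "33", "38",
       "42", "44", "48", "51", "55", "58", "88"]
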