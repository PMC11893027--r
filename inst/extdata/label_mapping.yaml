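# Default mapping from the 19-label fine parcellation to the 7 analysis
# categories. Raw label ids are a package convention (editable); categories
# must be one of: eCSF, gray_matter, white_matter, deep_gray_matter,
# ventricles, cerebellum, brainstem, discard.
mapping:
  "1": eCSF                 # eCSF, left
  "2": eCSF                 # eCSF, right
  "3": gray_matter          # cortical gray matter, left
  "4": gray_matter          # cortical gray matter, right
  "5": white_matter         # white matter, left
  "6": white_matter         # white matter, right
  "7": ventricles           # lateral ventricle, left
  "8": ventricles           # lateral ventricle, right
  "9": white_matter         # corpus callosum
  "10": ventricles          # third ventricle
  "11": ventricles          # fourth ventricle
  "12": deep_gray_matter    # thalamus, left
  "13": deep_gray_matter    # thalamus, right
  "14": deep_gray_matter    # basal ganglia, left
  "15": deep_gray_matter    # basal ganglia, right
  "16": cerebellum          # cerebellar hemisphere, left
  "17": cerebellum          # cerebellar hemisphere, right
  "18": cerebellum          # vermis
  "19": brainstem           # brainstem
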