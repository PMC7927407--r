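<?xml version="1.0" encoding="UTF-8"?>
<topics>
<topic number="2017-1"><disease>Liposarcoma</disease><gene>CDK4 Amplification</gene><demographic>38-year-old male</demographic><other>GERD</other></topic>
<topic number="2018-1"><disease>Melanoma</disease><gene>BRAF (V600E)</gene><demographic>64-year-old male</demographic><other>None</other></topic>
<topic number="2019-1"><disease>Melanoma</disease><gene>BRAF (E586K)</gene><demographic>64-year-old female</demographic><other>None</other></topic>
</topics>
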