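<?xml version="1.0" encoding="UTF-8"?>
<landmarks subject="example01" segment="first_metatarsal" units="mm">
  <landmark name="TL" x="61.25" y="4.10" z="-8.90"/>
  <landmark name="TM" x="60.80" y="5.35" z="9.70"/>
  <landmark name="TB" x="-2.15" y="3.05" z="11.20"/>
</landmarks>
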