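<Lems>
  <!-- Single-compartment cell with the classic squid-axon Na, K and leak
       conductances (modern -65 mV resting convention; absolute values
       for a nominal 1 cm^2 of membrane) and a step-current stimulus. -->
  <Include file="lems_core_types.xml"/>
  <Target component="sim1"/>

  <hhCell id="hhcell" C="1 uF" v0="-65 mV" threshSpike="0 mV">
    <ionChannelHH id="naChan" gbar="120 mS" erev="50 mV">
      <gateHHrates id="m" instances="3">
        <forwardRate type="expLinearRate" rate="1 per_ms"
                     midpoint="-40 mV" scale="10 mV"/>
        <reverseRate type="expRate" rate="4 per_ms"
                     midpoint="-65 mV" scale="-18 mV"/>
      </gateHHrates>
      <gateHHrates id="h" instances="1">
        <forwardRate type="expRate" rate="0.07 per_ms"
                     midpoint="-65 mV" scale="-20 mV"/>
        <reverseRate type="sigmoidRate" rate="1 per_ms"
                     midpoint="-35 mV" scale="10 mV"/>
      </gateHHrates>
    </ionChannelHH>
    <ionChannelHH id="kChan" gbar="36 mS" erev="-77 mV">
      <gateHHrates id="n" instances="4">
        <forwardRate type="expLinearRate" rate="0.1 per_ms"
                     midpoint="-55 mV" scale="10 mV"/>
        <reverseRate type="expRate" rate="0.125 per_ms"
                     midpoint="-65 mV" scale="-80 mV"/>
      </gateHHrates>
    </ionChannelHH>
    <ionChannelPassive id="leak" gbar="0.3 mS" erev="-54.387 mV"/>
    <pulseGenerator id="stim" delay="50 ms" duration="50 ms"
                    amplitude="10 uA"/>
  </hhCell>

  <Simulation id="sim1" length="120 ms" step="0.02 ms" target="hhcell">
    <OutputFile id="of1" fileName="hh_cell.dat">
      <OutputColumn id="v" quantity="v"/>
      <OutputColumn id="m" quantity="naChan/m/q"/>
      <OutputColumn id="h" quantity="naChan/h/q"/>
      <OutputColumn id="n" quantity="kChan/n/q"/>
      <OutputColumn id="istim" quantity="stim/i"/>
    </OutputFile>
    <EventOutputFile id="ev1" fileName="hh_cell.events"/>
  </Simulation>
</Lems>
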