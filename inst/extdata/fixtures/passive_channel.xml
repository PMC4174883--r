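<Lems>
  <!-- Ohmic channel on a single passive compartment.
       Closed form: v(t) = E + (v0 - E) exp(-t / (C/g)); here C/g = 20 ms. -->
  <Include file="lems_core_types.xml"/>
  <Target component="sim1"/>

  <passiveCell id="pasCell" C="1 nF" v0="-55 mV">
    <passiveChannel id="leak" g="50 nS" E="-65 mV"/>
  </passiveCell>

  <Simulation id="sim1" length="100 ms" step="0.02 ms" target="pasCell">
    <OutputFile id="of1" fileName="passive_channel.dat">
      <OutputColumn id="v" quantity="v"/>
      <OutputColumn id="I" quantity="leak/I"/>
    </OutputFile>
    <EventOutputFile id="ev1" fileName="passive_channel.events"/>
  </Simulation>
</Lems>
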