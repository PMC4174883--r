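<Lems>
  <!-- NMDA-like synapse with voltage/concentration-dependent block and
       two-variable presynaptic depression+facilitation, driven by a
       periodic spike source onto a voltage-clamped postsynaptic cell.
       Spikes reach the plasticity mechanism via the parent-to-child
       event relay declared in the synapse type. -->
  <Include file="lems_core_types.xml"/>
  <Target component="sim1"/>

  <blockingPlasticSynapse id="nmdaSyn" gbase="1 nS" erev="0 mV"
                          tauDecay="10 ms">
    <blockMechanism type="voltageConcDepBlockMechanism"
                    blockConcentration="2 mM" scalingConc="1.9 mM"
                    scalingVolt="16.13 mV"/>
    <plasticityMechanism type="tsodyksMarkramDepFacMechanism"
                         initReleaseProb="0.5" tauRec="120 ms"
                         tauFac="10 ms"/>
  </blockingPlasticSynapse>

  <network id="net1">
    <spikeGenerator id="gen1" period="20 ms"/>
    <voltageClampCell id="post" vHold="100 mV"/>
    <explicitConnection id="conn1" from="gen1" to="post" synapse="nmdaSyn"
                        delay="1 ms" weight="1"/>
  </network>

  <Simulation id="sim1" length="200 ms" step="0.05 ms" target="net1">
    <OutputFile id="of1" fileName="blocking_plastic_synapse.dat">
      <OutputColumn id="g" quantity="post/synapses[0]/g"/>
      <OutputColumn id="R"
                    quantity="post/synapses[0]/plasticityMechanism/R"/>
      <OutputColumn id="U"
                    quantity="post/synapses[0]/plasticityMechanism/U"/>
      <OutputColumn id="isyn" quantity="post/iSyn"/>
    </OutputFile>
    <EventOutputFile id="ev1" fileName="blocking_plastic_synapse.events"/>
  </Simulation>
</Lems>
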