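<?xml version="1.0" encoding="UTF-8"?>
<entrySet xmlns="http://psi.hupo.org/mi/mif300" level="3" version="0" minorVersion="0">
  <entry>
    <experimentList>
      <experimentDescription id="1">
        <bibref>
          <xref>
            <primaryRef db="pubmed" id="7000018"/>
          </xref>
        </bibref>
        <hostOrganismList>
          <hostOrganism ncbiTaxId="9606">
            <names>
              <shortLabel>human</shortLabel>
            </names>
          </hostOrganism>
        </hostOrganismList>
        <interactionDetectionMethod>
          <names>
            <shortLabel>two hybrid</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0018" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactionDetectionMethod>
      </experimentDescription>
    </experimentList>
    <interactorList>
      <interactor id="2">
        <names>
          <shortLabel>iris_e</shortLabel>
        </names>
        <interactorType>
          <names>
            <shortLabel>protein</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0326" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactorType>
        <organism ncbiTaxId="9606">
          <names>
            <shortLabel>human</shortLabel>
          </names>
        </organism>
      </interactor>
      <interactor id="3">
        <names>
          <shortLabel>juniper_m</shortLabel>
        </names>
        <interactorType>
          <names>
            <shortLabel>protein</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0326" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactorType>
        <organism ncbiTaxId="9606">
          <names>
            <shortLabel>human</shortLabel>
          </names>
        </organism>
      </interactor>
      <interactor id="4">
        <names>
          <shortLabel>kestrel_s</shortLabel>
        </names>
        <interactorType>
          <names>
            <shortLabel>protein</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0326" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactorType>
        <organism ncbiTaxId="9606">
          <names>
            <shortLabel>human</shortLabel>
          </names>
        </organism>
      </interactor>
    </interactorList>
    <interactionList>
      <interaction id="5">
        <experimentList>
          <experimentRef>1</experimentRef>
        </experimentList>
        <participantList>
          <participant id="6">
            <interactorRef>2</interactorRef>
            <experimentalRoleList>
              <experimentalRole>
                <names>
                  <shortLabel>bait</shortLabel>
                </names>
                <xref>
                  <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0496" refType="identity" refTypeAc="MI:0356"/>
                </xref>
              </experimentalRole>
            </experimentalRoleList>
          </participant>
          <participant id="7">
            <interactorRef>4</interactorRef>
            <experimentalRoleList>
              <experimentalRole>
                <names>
                  <shortLabel>prey</shortLabel>
                </names>
                <xref>
                  <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0498" refType="identity" refTypeAc="MI:0356"/>
                </xref>
              </experimentalRole>
            </experimentalRoleList>
          </participant>
        </participantList>
        <interactionType>
          <names>
            <shortLabel>physical association</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0915" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactionType>
      </interaction>
      <abstractInteraction id="10">
        <names>
          <shortLabel>iris-juniper allosteric module</shortLabel>
        </names>
        <interactorType>
          <names>
            <shortLabel>complex</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0314" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactorType>
        <participantList>
          <participant id="8">
            <interactorRef>2</interactorRef>
          </participant>
          <participant id="9">
            <interactorRef>3</interactorRef>
          </participant>
        </participantList>
        <cooperativeEffectList>
          <allostery>
            <cooperativeEffectEvidenceList>
              <cooperativeEffectEvidence>
                <bibref>
                  <xref>
                    <primaryRef db="pubmed" id="7000019"/>
                  </xref>
                </bibref>
                <evidenceMethodList>
                  <evidenceMethod>
                    <names>
                      <shortLabel>inferred by author</shortLabel>
                    </names>
                    <xref>
                      <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0363" refType="identity" refTypeAc="MI:0356"/>
                    </xref>
                  </evidenceMethod>
                </evidenceMethodList>
              </cooperativeEffectEvidence>
            </cooperativeEffectEvidenceList>
            <affectedInteractionList>
              <affectedInteractionRef>5</affectedInteractionRef>
            </affectedInteractionList>
            <cooperativeEffectOutcome>
              <names>
                <shortLabel>positive cooperative effect</shortLabel>
              </names>
            </cooperativeEffectOutcome>
            <cooperativeEffectResponse>
              <names>
                <shortLabel>altered physicochemical compatibility</shortLabel>
              </names>
            </cooperativeEffectResponse>
            <allostericMoleculeRef>8</allostericMoleculeRef>
            <moleculeEffectorRef>9</moleculeEffectorRef>
          </allostery>
        </cooperativeEffectList>
      </abstractInteraction>
    </interactionList>
  </entry>
</entrySet>
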